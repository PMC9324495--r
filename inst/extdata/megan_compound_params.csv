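compound_class,compound,beta,ldf,ct1,ceo,a_new,a_gro,a_mat,a_old
isoprene,Isoprene,0.13,1.0,95,2.00,0.05,0.60,1.00,0.90
monoterpene,Myrcene,0.10,0.6,80,1.83,2.00,1.80,1.00,1.05
monoterpene,Sabinene,0.10,0.6,80,1.83,2.00,1.80,1.00,1.05
monoterpene,Limonene,0.10,0.2,80,1.83,2.00,1.80,1.00,1.05
monoterpene,3-Carene,0.10,0.2,80,1.83,2.00,1.80,1.00,1.05
monoterpene,t-b-Ocimene,0.10,0.8,80,1.83,2.00,1.80,1.00,1.05
monoterpene,b-Pinene,0.10,0.2,80,1.83,2.00,1.80,1.00,1.05
monoterpene,a-Pinene,0.10,0.6,80,1.83,2.00,1.80,1.00,1.05
monoterpene,Other Monoterpenes,0.10,0.4,80,1.83,2.00,1.80,1.00,1.05
sesquiterpene,a-Farnesene,0.17,0.5,130,2.37,0.40,0.60,1.00,0.95
sesquiterpene,b-Caryophyllene,0.17,0.5,130,2.37,0.40,0.60,1.00,0.95
sesquiterpene,Other Sesquiterpenes,0.17,0.5,130,2.37,0.40,0.60,1.00,0.95
other_voc,232-MBO,0.13,1.0,95,2.00,0.05,0.60,1.00,0.90
other_voc,Methanol,0.08,0.8,60,1.60,3.50,3.00,1.00,1.20
other_voc,Acetone,0.10,0.2,80,1.83,1.00,1.00,1.00,1.00
other_voc,CO,0.08,1.0,60,1.60,1.00,1.00,1.00,1.00
other_voc,Bidirectional VOC,0.13,0.8,95,2.00,1.00,1.00,1.00,1.00
other_voc,Stress VOC,0.10,0.8,80,1.83,1.00,1.00,1.00,1.00
other_voc,Other VOCs,0.10,0.2,80,1.83,1.00,1.00,1.00,1.00
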