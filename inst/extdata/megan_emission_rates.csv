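compound_class,compound,needleleaf_conifer,broadleaf_deciduous
isoprene,Isoprene,600,10000
monoterpene,Myrcene,70,30
monoterpene,Sabinene,70,50
monoterpene,Limonene,100,80
monoterpene,3-Carene,160,30
monoterpene,t-b-Ocimene,70,120
monoterpene,b-Pinene,300,130
monoterpene,a-Pinene,500,400
monoterpene,Other Monoterpenes,180,150
sesquiterpene,a-Farnesene,40,40
sesquiterpene,b-Caryophyllene,80,40
sesquiterpene,Other Sesquiterpenes,120,100
other_voc,232-MBO,700,0.01
other_voc,Methanol,900,900
other_voc,Acetone,240,240
other_voc,CO,600,600
other_voc,Bidirectional VOC,500,500
other_voc,Stress VOC,300,300
other_voc,Other VOCs,140,140
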