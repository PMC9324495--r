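season,compound_class,mean,sd
spring,monoterpene,175.6,140.6
spring,sesquiterpene,18.1,23.9
summer,monoterpene,688.5,239.7
summer,sesquiterpene,123.9,74.0
autumn,monoterpene,259.3,172.2
autumn,sesquiterpene,29.5,29.4
winter,monoterpene,45.5,22.6
winter,sesquiterpene,1.8,1.6
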