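nutrient,sex,age_min,age_max,ear,ul
vit_d,M,19,120,10,100
vit_d,F,19,120,10,100
calcium,M,19,70,800,2500
calcium,M,71,120,1000,2000
calcium,F,19,50,800,2500
calcium,F,51,120,1000,2000
vit_b12,M,19,120,2.0,
vit_b12,F,19,120,2.0,
iron,M,19,120,6,45
iron,F,19,50,8.1,45
iron,F,51,120,5,45
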