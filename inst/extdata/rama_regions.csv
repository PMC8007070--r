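class,region,vertex,phi,psi
generic,beta_extended,1,-180,85
generic,beta_extended,2,-45,85
generic,beta_extended,3,-45,180
generic,beta_extended,4,-180,180
generic,alpha_R,1,-160,-120
generic,alpha_R,2,-20,-120
generic,alpha_R,3,-20,30
generic,alpha_R,4,-160,30
generic,alpha_L,1,20,-30
generic,alpha_L,2,160,-30
generic,alpha_L,3,160,120
generic,alpha_L,4,20,120
gly,beta_extended,1,-180,85
gly,beta_extended,2,-45,85
gly,beta_extended,3,-45,180
gly,beta_extended,4,-180,180
gly,alpha_R,1,-160,-120
gly,alpha_R,2,-20,-120
gly,alpha_R,3,-20,30
gly,alpha_R,4,-160,30
gly,alpha_L,1,20,-30
gly,alpha_L,2,180,-30
gly,alpha_L,3,180,130
gly,alpha_L,4,20,130
pro,beta_extended,1,-110,85
pro,beta_extended,2,-40,85
pro,beta_extended,3,-40,180
pro,beta_extended,4,-110,180
pro,alpha_R,1,-110,-60
pro,alpha_R,2,-40,-60
pro,alpha_R,3,-40,10
pro,alpha_R,4,-110,10
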