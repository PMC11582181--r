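item_id,state_index,alpha,beta_1,beta_2,beta_3,beta_4,beta_5,beta_6,loading
M1,1,1.888,-0.708,0.607,1.42,2.075,3.244,4.345,0.803
M2,1,1.324,-5.367,-4.835,-2.068,1.2,2.713,3.607,0.315
M3,1,4.349,-3.306,-2.856,-0.387,1.047,2.221,3.134,0.679
S1,2,3.397,-3.185,-3.092,-1.979,-0.607,3.173,,-0.409
S2,2,2.99,-3.661,-3.025,-2.515,-1.959,-1.174,,-0.34
S3,2,3.462,-3.123,-2.388,-0.596,0.7,3.251,,-0.605
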