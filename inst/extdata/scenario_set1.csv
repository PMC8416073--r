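"set_id","sim","coupling","p_ag","p_tf","l_ag","l_blimp1","l_bcl6","l_irf4"
1,1,"none",0,0,0.5,0.5,0.5,0.5
1,2,"tf_only",0,0.72,0.5,1,1,1
1,3,"ag_only",0.72,0,1,0.5,0.5,0.5
1,4,"coupled",0.72,0.72,1,1,1,1
1,5,"coupled",0.72,0.72,1,0.9,0.9,0.9
1,6,"coupled",0.72,0.72,1,0.75,0.75,0.75
1,7,"uncoupled",0.72,1,1,1,1,1
1,8,"uncoupled",0.72,1,1,0.9,0.9,0.9
1,9,"uncoupled",0.72,1,1,0.75,0.75,0.75
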