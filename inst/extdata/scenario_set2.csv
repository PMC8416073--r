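"set_id","sim","coupling","p_ag","p_tf","l_ag","l_blimp1","l_bcl6","l_irf4"
2,1,"coupled",0.72,0.72,1,1,1,1
2,2,"coupled",0.72,0.72,1,0.9,1,1
2,3,"coupled",0.72,0.72,1,0.75,1,1
2,4,"coupled",0.72,0.72,1,1,0.9,1
2,5,"coupled",0.72,0.72,1,0.9,0.9,1
2,6,"coupled",0.72,0.72,1,0.75,0.9,1
2,7,"coupled",0.72,0.72,1,1,0.75,1
2,8,"coupled",0.72,0.72,1,0.9,0.75,1
2,9,"coupled",0.72,0.72,1,0.75,0.75,1
2,10,"coupled",0.72,0.72,1,1,1,0.9
2,11,"coupled",0.72,0.72,1,0.9,1,0.9
2,12,"coupled",0.72,0.72,1,0.75,1,0.9
2,13,"coupled",0.72,0.72,1,1,0.9,0.9
2,14,"coupled",0.72,0.72,1,0.9,0.9,0.9
2,15,"coupled",0.72,0.72,1,0.75,0.9,0.9
2,16,"coupled",0.72,0.72,1,1,0.75,0.9
2,17,"coupled",0.72,0.72,1,0.9,0.75,0.9
2,18,"coupled",0.72,0.72,1,0.75,0.75,0.9
2,19,"coupled",0.72,0.72,1,1,1,0.75
2,20,"coupled",0.72,0.72,1,0.9,1,0.75
2,21,"coupled",0.72,0.72,1,0.75,1,0.75
2,22,"coupled",0.72,0.72,1,1,0.9,0.75
2,23,"coupled",0.72,0.72,1,0.9,0.9,0.75
2,24,"coupled",0.72,0.72,1,0.75,0.9,0.75
2,25,"coupled",0.72,0.72,1,1,0.75,0.75
2,26,"coupled",0.72,0.72,1,0.9,0.75,0.75
2,27,"coupled",0.72,0.72,1,0.75,0.75,0.75
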