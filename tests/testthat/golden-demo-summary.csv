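"metric","value"
"transport.v_max_um_s.head2",2.00000000000007
"transport.re_max.head2",0.000500000000000018
"transport.v_max_um_s.head10",10.0000000000003
"transport.re_max.head10",0.00250000000000009
"transport.v_max_um_s.head20",20.0000000000007
"transport.re_max.head20",0.00500000000000017
"transport.formation_time_s",1800
"fibers.coefficient.aligned",0.967643642311054
"fibers.coefficient.random",0.049644341400249
"frap.speed_um_s.true2",1.99127551753877
"frap.speed_um_s.true10",9.97155457522594
"cysts.curvature_ratio.control",0.964489847004374
"cysts.shape_factor.control",0.725934319419964
"cysts.roundness.control",0.808377387705988
"cysts.curvature_ratio.gradient",2.96025176787773
"cysts.shape_factor.gradient",0.470717258687892
"cysts.roundness.gradient",0.915908508194148
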