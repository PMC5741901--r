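mirna,hc_median,hc_q1,hc_q3,ccp_median,ccp_q1,ccp_q3,vera_median,vera_q1,vera_q3,fd_ccp_hc,fd_vera_hc,ddct_median,ddct_q1,ddct_q3,fc_median,n_up,n_evaluable,low_expression,mean_fc_rescue,age_adjust_drop,literature,newly_expressed
miR-16,-6.3,-7.1,-6.0,-7.1,-7.6,-7.0,-7.6,-8.2,-7.4,1.7,2.4,-0.4,-1.1,-0.1,1.3,10,12,FALSE,FALSE,FALSE,TRUE,FALSE
miR-18a,0.1,-0.8,1.3,1.3,0.3,2.0,-0.1,-1.0,0.4,-2.4,1.1,-1.6,-2.0,-1.0,3.1,10,12,FALSE,FALSE,FALSE,TRUE,FALSE
miR-19a,-0.9,-1.6,1.0,-2.4,-2.8,-1.9,-3.2,-3.5,-2.8,2.9,5.0,-0.6,-1.7,0.1,1.5,9,12,FALSE,FALSE,FALSE,FALSE,FALSE
miR-21,-2.8,-4.1,-2.5,-3.8,-4.4,-3.3,-4.3,-4.8,-4.1,2.0,2.7,-0.7,-1.2,-0.2,1.6,9,12,FALSE,FALSE,FALSE,TRUE,FALSE
miR-22,4.2,0.5,4.8,3.0,1.5,5.1,0.9,0.6,1.5,2.2,9.4,-2.1,-3.6,-1.5,4.3,12,12,FALSE,FALSE,FALSE,FALSE,FALSE
miR-26b,-1.4,-3.0,0.2,-3.1,-3.4,-1.8,-3.6,-4.2,-2.8,3.3,4.7,-0.7,-2.3,-0.3,1.7,10,12,FALSE,FALSE,FALSE,FALSE,FALSE
miR-34a,-0.2,-2.1,0.8,-0.1,-0.3,1.0,-0.6,-2.1,0.2,-1.1,1.3,-0.1,-0.9,0.3,1.1,6,12,FALSE,FALSE,FALSE,TRUE,FALSE
miR-101,2.5,1.7,3.2,1.6,1.3,1.8,0.4,-0.3,0.9,1.9,4.3,-1.1,-1.9,-0.6,2.1,11,12,FALSE,FALSE,FALSE,FALSE,FALSE
miR-132,-1.6,-2.0,-1.4,-1.7,-2.1,-1.6,-2.5,-2.7,-2.2,1.0,1.8,-0.8,-1.1,-0.3,1.7,11,12,FALSE,FALSE,FALSE,TRUE,FALSE
miR-142-3p,-2.3,-4.5,-1.3,-4.4,-4.5,-3.8,-5.0,-5.2,-4.5,4.2,6.2,-0.4,-1.1,-0.3,1.4,10,12,FALSE,FALSE,FALSE,FALSE,FALSE
miR-142-5p,3.9,2.9,5.7,3.0,2.4,5.5,1.7,1.5,4.3,1.9,4.7,-1.3,-1.4,-0.3,2.4,10,12,FALSE,FALSE,FALSE,FALSE,FALSE
miR-146a,-7.3,-7.5,-6.5,-7.1,-7.6,-7.0,-7.5,-7.7,-7.3,-1.2,1.1,-0.5,-0.8,0.2,1.4,8,12,FALSE,FALSE,FALSE,TRUE,FALSE
miR-155,-0.9,-2.3,1.5,0.1,-0.5,1.1,-0.5,-0.7,-0.3,-2.1,-1.4,-0.3,-1.3,0.1,1.2,8,12,FALSE,FALSE,FALSE,TRUE,FALSE
miR-195,-2.5,-3.0,-1.6,-0.4,-3.4,0.2,-2.9,-4.2,-0.5,-4.6,1.3,-1.1,-2.0,-0.5,2.1,11,12,FALSE,FALSE,FALSE,FALSE,FALSE
miR-197,-3.5,-3.3,-1.3,0.6,-1.5,2.9,0.6,-2.5,2.2,-16.8,-16.5,-0.6,-2.7,1.3,1.5,7,12,FALSE,FALSE,FALSE,FALSE,FALSE
miR-203,2.3,1.8,3.0,3.0,2.1,3.0,2.9,2.6,3.4,-1.5,-1.5,0.0,-0.4,0.6,1.0,6,12,FALSE,FALSE,FALSE,TRUE,FALSE
miR-210,3.9,0.1,5.0,3.1,2.2,3.4,1.5,1.1,1.8,1.8,5.1,-1.8,-2.9,-0.3,3.4,10,12,FALSE,FALSE,FALSE,FALSE,FALSE
miR-223,-9.3,-9.6,-8.8,-9.9,-9.9,-9.6,-10.3,-10.4,-10.0,1.5,2.0,-0.4,-0.6,0.2,1.3,6,9,FALSE,FALSE,FALSE,TRUE,FALSE
miR-361,-0.1,-1.1,1.1,2.1,-0.5,2.5,0.6,-0.2,0.7,-4.7,-1.7,-1.5,-2.1,-1.0,2.9,11,12,FALSE,FALSE,FALSE,FALSE,FALSE
miR-374,-2.2,-3.4,-2.1,-3.2,-3.7,-2.0,-4.1,-4.3,-3.9,2.0,3.8,-0.6,-1.0,-0.4,1.5,12,12,FALSE,FALSE,TRUE,FALSE,FALSE
miR-382,-0.7,-1.2,0.5,1.4,0.9,2.7,-0.1,-1.2,0.5,-4.1,-1.5,-2.0,-2.8,-0.8,4.1,11,12,FALSE,FALSE,FALSE,FALSE,FALSE
miR-454,-1.3,-2.8,0.2,-2.3,-3.2,-0.1,-3.0,-3.3,-1.3,1.9,3.3,-0.5,-1.1,-0.2,1.4,10,12,FALSE,FALSE,TRUE,FALSE,FALSE
miR-486-3p,4.3,2.5,5.6,4.9,2.5,6.2,3.5,3.1,4.3,-1.5,1.8,-2.0,-3.1,0.2,4.1,9,12,FALSE,FALSE,FALSE,FALSE,FALSE
miR-520c-3p,2.3,0.3,2.9,-0.4,-1.6,2.4,-1.1,-1.4,0.5,6.3,10.6,0.3,-1.7,0.6,-1.3,5,12,FALSE,FALSE,FALSE,FALSE,FALSE
miR-579,4.2,3.5,5.0,3.5,3.1,3.7,2.4,1.8,2.9,1.6,3.6,-1.2,-1.7,-0.3,2.2,11,12,FALSE,TRUE,FALSE,FALSE,FALSE
miR-590-3P,5.2,2.9,5.8,3.2,2.3,3.9,2.4,2.2,3.1,3.9,6.9,-0.9,-1.1,0.2,1.9,8,12,FALSE,FALSE,FALSE,FALSE,FALSE
miR-590-5p,1.2,0.7,1.4,-0.4,-1.2,-0.2,-1.3,-1.6,-0.7,3.0,5.6,-0.5,-1.1,-0.3,1.4,10,12,FALSE,FALSE,FALSE,FALSE,FALSE
miR-598,3.7,3.1,4.3,2.8,2.5,3.6,1.5,1.4,1.9,1.8,4.6,-1.2,-1.7,-0.8,2.2,12,12,FALSE,FALSE,FALSE,FALSE,FALSE
miR-628-5p,3.0,-8.4,7.9,-7.2,-8.3,3.9,-2.9,-7.8,2.2,1174.6,61.3,0.4,-1.6,1.7,-1.3,5,12,FALSE,FALSE,FALSE,FALSE,FALSE
miR-15b#,9.9,2.6,11.4,6.2,5.6,8.4,4.0,2.0,4.4,13.3,58.5,-2.6,-4.0,-1.8,6.1,11,11,TRUE,FALSE,FALSE,FALSE,TRUE
miR-335#,6.1,5.6,8.3,6.5,5.2,8.1,4.2,3.9,5.1,-1.4,3.6,-1.9,-3.9,-1.0,3.8,12,12,TRUE,FALSE,FALSE,FALSE,TRUE
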