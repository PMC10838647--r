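individual_id,class,time_min,gc_value,gr_expression
ind_001,baseline,1.65700233913958,2.99655772028304,2.61221599544774
ind_001,stress_induced,20.6682695378549,25.7943783588016,2.61221599544774
ind_001,post_dex,72.1931079728529,6.8725159667648,2.61221599544774
ind_001,post_acth,100,44.4731768394758,2.61221599544774
ind_002,baseline,2.43586981901899,3.27589079077665,10.5723921786739
ind_002,stress_induced,20.8843233808875,24.8369566595599,10.5723921786739
ind_002,post_dex,63.6607149755582,7.17111526361974,10.5723921786739
ind_002,post_acth,100,43.4812064874727,10.5723921786739
ind_003,baseline,1.44439976708964,2.40386904249385,4.78625851452871
ind_003,stress_induced,20.5725754797459,27.7217107690189,4.78625851452871
ind_003,post_dex,70.4878974007443,6.94286901223603,4.78625851452871
ind_003,post_acth,100,41.674135038068,4.78625851452871
ind_004,baseline,2.20965556008741,3.52949956466314,3.25478101704361
ind_004,stress_induced,29.7727950150147,24.1439429635144,3.25478101704361
ind_004,post_dex,72.9623882472515,6.02205737098306,3.25478101704361
ind_004,post_acth,100,49.5977938634364,3.25478101704361
ind_005,baseline,2.88866566959769,4.35546096428292,5.11201895459836
ind_005,stress_induced,29.2982826684602,24.9667733728219,5.11201895459836
ind_005,post_dex,60.9831893630326,10.1873880732632,5.11201895459836
ind_005,post_acth,100,57.1437915927173,5.11201895459836
ind_006,baseline,2.74178236210719,3.45083204508989,2.75346850685764
ind_006,stress_induced,27.6114023919217,26.2191924025959,2.75346850685764
ind_006,post_dex,73.4398905886337,5.30093186641672,2.75346850685764
ind_006,post_acth,100,48.670642123592,2.75346850685764
ind_007,baseline,0.385439367033541,2.67199304189417,2.46465509238607
ind_007,stress_induced,24.4054306996986,27.9262725738845,2.46465509238607
ind_007,post_dex,72.2400269052014,6.57600187077294,2.46465509238607
ind_007,post_acth,100,43.7984301615742,2.46465509238607
ind_008,baseline,2.57179670780897,4.23177449522527,2.93490097454004
ind_008,stress_induced,20.7862640242092,28.7114868771837,2.93490097454004
ind_008,post_dex,61.2500107707456,9.49802618438618,2.93490097454004
ind_008,post_acth,100,47.0718661279217,2.93490097454004
ind_009,baseline,0.862244653282687,2.00226758177709,7.01247757438611
ind_009,stress_induced,24.3137618713081,24.2568148531313,7.01247757438611
ind_009,post_dex,64.1489220317453,6.90179317808706,7.01247757438611
ind_009,post_acth,100,40.5731378327958,7.01247757438611
ind_010,baseline,2.95939248776995,5.07142445077396,1.4642638722317
ind_010,stress_induced,26.1566087394021,27.0377107122269,1.4642638722317
ind_010,post_dex,62.1837553801015,8.79845645550923,1.4642638722317
ind_010,post_acth,100,50.6023487223541,1.4642638722317
ind_011,baseline,0.448494836920872,3.20835874593617,2.17099601386086
ind_011,stress_induced,26.9944696128368,29.2395940567698,2.17099601386086
ind_011,post_dex,61.611585044302,8.58934334793576,2.17099601386086
ind_011,post_acth,100,60.1219817128033,2.17099601386086
ind_012,baseline,2.35342477401718,3.65345063611942,2.2728969688091
ind_012,stress_induced,21.694930808153,29.3746358218206,2.2728969688091
ind_012,post_dex,66.74268478062,6.75646118664144,2.2728969688091
ind_012,post_acth,100,50.0565891912966,2.2728969688091
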