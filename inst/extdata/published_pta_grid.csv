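crcl,total_daily_dose,dose,tau,tinf,p_gt_12,p_gt_46,bound_46
160,3000,1500,12,0.5,51,0.5,TRUE
160,3000,1500,12,4,62,0.5,TRUE
160,3000,1500,12,6,70,0.5,TRUE
160,3000,1000,8,0.5,65,0.5,TRUE
160,3000,1000,8,4,81,0.5,TRUE
160,3000,1000,8,6,88,1,FALSE
160,3000,3000,24,24,98,1,FALSE
160,4500,1500,8,0.5,89,5,FALSE
200,3000,1000,8,6,69,0.5,TRUE
200,3000,3000,24,24,89,0.5,TRUE
200,4500,1500,8,4,84,1,FALSE
200,4500,1500,8,6,92,2,FALSE
200,6000,2000,8,0.5,84,5,FALSE
240,3000,3000,24,24,68,0.5,TRUE
240,4500,1500,8,4,61,0.5,TRUE
240,4500,1500,8,6,74,0.5,TRUE
240,4500,4500,24,24,96,1,FALSE
240,6000,2000,8,4,80,2,FALSE
240,6000,2000,8,6,89,3,FALSE
240,6000,6000,24,24,99,7,FALSE
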