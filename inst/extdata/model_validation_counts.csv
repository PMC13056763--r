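session,usg_cutoff,variable,auc,sensitivity_pct,specificity_pct,tp,tn,fp,fn
morning,low,model,0.72,66.7,62.5,32,20,12,16
morning,low,intake,0.64,66.7,53.1,32,17,15,16
morning,low,frequency,0.65,68.8,59.4,33,19,13,15
morning,low,volume,0.53,85.4,21.9,41,7,25,7
morning,low,color,0.58,60.4,53.1,29,17,15,19
afternoon,low,model,0.85,73.7,75.9,28,22,7,10
afternoon,low,intake,0.71,84.2,58.6,32,17,12,6
afternoon,low,frequency,0.63,63.2,62.1,24,18,11,14
afternoon,low,volume,0.67,68.4,65.5,26,19,10,12
afternoon,low,color,0.68,86.8,51.7,33,15,14,5
morning,high,model,0.81,59.7,87.5,43,7,1,29
morning,high,intake,0.66,59.7,50.0,43,4,4,29
morning,high,frequency,0.69,61.1,75.0,44,6,2,28
morning,high,volume,0.59,84.7,37.5,61,3,5,11
morning,high,color,0.68,58.3,75.0,42,6,2,30
afternoon,high,model,0.86,60.3,90.0,35,9,1,23
afternoon,high,intake,0.65,70.7,60.0,41,6,4,17
afternoon,high,frequency,0.68,58.6,80.0,34,8,2,24
afternoon,high,volume,0.67,60.3,80.0,35,8,2,23
afternoon,high,color,0.72,77.6,70.0,45,7,3,13
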