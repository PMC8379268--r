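"participant_id","block","trial_id","true_label","decision","response_timestamp_s","reported_confidence","confidence_timestamp_s","correctness"
"P01",1,1,-1,1,2.53512980675608,10,4.31360424448088,"incorrect"
"P01",1,2,0,,,,,
"P01",1,3,1,1,14.3590216276534,90,14.9755915500522,"correct"
"P01",1,4,-1,-1,21.0226433592559,100,22.5529519675243,"correct"
"P01",1,5,0,,,,,
"P01",1,6,1,1,32.4622906644142,90,33.7024523942045,"correct"
"P02",1,1,-1,-1,2.93146804742294,90,3.97623312970402,"correct"
"P02",1,2,0,,,,,
"P02",1,3,1,-1,14.6603709359152,40,15.8420491833437,"incorrect"
"P02",1,4,-1,-1,21.0742855557452,100,22.1546972903867,"correct"
"P02",1,5,0,,,,,
"P02",1,6,1,1,32.5809466345292,80,34.1836747746272,"correct"
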