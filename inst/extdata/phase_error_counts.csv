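stage,phase,error_type,count
pre-treatment,assessment of patient,ICD implantation is not considered,3
pre-treatment,simulation,wrong treatment field size,1
pre-treatment,simulation,machine breakdown,1
pre-treatment,delineation,wrong definition,9
pre-treatment,delineation,wrong CT image used,2
pre-treatment,delineation,wrong registration,1
pre-treatment,treatment planning,wrong data transfer or setting,17
pre-treatment,treatment planning,treatment history not considered,4
pre-treatment,treatment planning,organ at risk dose out of limits,4
pre-treatment,treatment planning,wrong structure copy,2
pre-treatment,planning approval,the wrong treatment plan passed,4
treatment,patient exchange,patient ID not verified,3
treatment,wrong patient set-up,markers not correctly identified or wrong verification,15
treatment,wrong delivery,repeated irradiation or missed irradiation,12
treatment,no attention to the treatment room,collision of gantry and couch,2
treatment,patient status was not observed,patient has difficulty breathing,1
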