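variable,category,nPTSD,fPTSD,sPTSD
sex,Male,4,4,3
sex,Female,13,15,17
marital_status,Single,11,14,17
marital_status,Married,6,5,3
occupation,Employed,7,2,6
occupation,Unemployed,1,2,0
occupation,Student,9,14,13
occupation,Retired,0,1,1
education,Standard,9,16,15
education,Higher,8,3,5
medication,No,15,10,17
medication,Yes,2,9,3
trauma_type,Accidental,8,4,7
trauma_type,Interpersonal,8,13,11
trauma_type,Both,1,2,2
number_of_traumas,Single,13,14,15
number_of_traumas,Multiple,4,5,5
meditation,No,14,12,13
meditation,Yes,3,7,7
handedness,Right,15,18,18
handedness,Left,2,1,2
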