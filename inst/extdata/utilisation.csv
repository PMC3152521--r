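event_id,label,gp,specialist_initial,specialist_followup,psychologist,health_practitioner,alternative_health_practitioner,prescription,nonprescription,transport
no_treatment,Do not seek treatment,0,0,0,0,0,0,0,0,0
seek,Seek treatment,0,0,0,0,0,0,0,0,0
1,Pharmacist,0,0,0,0,0,0,0,1.0,1.0
1.1,Refer General Practitioner,1.0,0,0,0,0,0,1.0,0,1.0
1.2,Success,0,0,0,0,0,0,0,0,0
2,General Practitioner,1.0,0,0,0,0,0,0,0,1.0
2.1,No further action,0,0,0,0,0,0,0,0,0
2.2,Treat,0,0,0,0,0,0,1.0,0,0
2.2.1,Success,0,0,0,0,0,0,0,0,0
2.2.2,Refer,0,0,0,0,0,0,0,0,0
2.2.2.1,Psychologist,0,0,0,4.0,0,0,0,0,4.0
2.2.2.2,Specialist Physician,0,1.0,1.0,0,0,0,1.0,0,2.0
2.2.2.3,Health Practitioner,0,0,0,0,2.0,0,0,0,2.0
3,Health Practitioner,0,0,0,0,1.0,0,0,0,1.0
3.1,No further action,0,0,0,0,0,0,0,0,0
3.2,Treat,0,0,0,0,0,0,0.5,0,0
3.2.1,Success,0,0,0,0,0,0,0,0,0
3.2.2,Refer,0,0,0,0,0,0,0,0,0
3.2.2.1,Psychologist,0,0,0,4.0,0,0,0,0,4.0
3.2.2.2,Specialist Physician,0,1.0,1.0,0,0,0,1.0,0,2.0
3.2.2.3,General Practitioner,1.0,0,0,0,0,0,1.0,0,1.0
3.2.2.4,Other Health Practitioner,0,0,0,0,3.0,0,0.5,0,3.0
4,Psychologist,0,0,0,1.0,0,0,0,0,1.0
4.1,No further action,0,0,0,0,0,0,0,0,0
4.2,Treat,0,0,0,0,0,0,0,0,0
4.2.1,Success,0,0,0,0,0,0,0,0,0
4.2.2,Refer/no further action,0,0,0,0,0,0,0,0,0
4.2.2.1,Other Psychologist,0,0,0,4.0,0,0,0,0,4.0
4.2.2.2,Specialist Physician,0,1.0,1.0,0,0,0,1.0,0,2.0
4.2.2.3,General Practitioner,1.0,0,0,0,0,0,1.0,0,1.0
4.2.2.4,No further action,0,0,0,0,0,0,0,0,0
5,Alternative Health Practitioner,0,0,0,0,0,1.0,0,0,1.0
5.1,No further action,0,0,0,0,0,0,0,0,0
5.2,Treat,0,0,0,0,0,2.0,0,0,2.0
5.2.2,Success,0,0,0,0,0,0,0,0,0
5.2.3,Refer/no further action,0,0,0,0,0,0,0,0,0
5.2.3.1,Other Alternative Health Practitioner,0,0,0,0,0,2.0,0,0,2.0
5.2.3.2,General Practitioner,1.0,0,0,0,0,0,0,0,1.0
5.2.3.3,No further action,0,0,0,0,0,0,0,0,0
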