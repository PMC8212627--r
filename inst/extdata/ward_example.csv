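measured_at,patient_id,case_id,order_id,parameter,value,units
2021-03-01T06:10:00,1002,C1002,O0001,K,4.1,mmol/L
2021-03-01T06:10:00,1002,C1002,O0001,NA,139,mmol/L
2021-03-01T07:45:00,1003,C1003,O0002,LACTATE,1.2,mmol/L
2021-03-01T08:00:00,1002,C1002,O0003,K,2.3,mmol/L
2021-03-01T08:30:00,1005,C1005,O0004,CREA,1.0,mg/dL
2021-03-01T09:15:00,1004,C1004,O0005,CA_ION,2.2,mmol/L
2021-03-01T11:05:00,1002,C1002,O0006,K,3.1,mmol/L
2021-03-02T08:30:00,1005,C1005,O0007,CREA,190,umol/L
2021-03-02T09:00:00,1003,C1003,O0008,LACTATE,5.6,mmol/L
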