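claim_id,patient_id,service_date,cost
1,P01,2018-01-25,100
2,P01,2018-04-15,50
3,P02,2018-02-20,80
4,P03,2018-03-01,40
5,P06,2018-09-07,60
6,P06,2018-09-08,70
7,P09,2018-09-15,90
8,P07,2018-05-02,30
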