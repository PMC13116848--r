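claim_id,patient_id,provider_id,admission_date,discharge_date,main_dx,has_thrombectomy,has_thrombolysis,cost
1,P01,PRV1,2018-01-10,2018-01-20,I63.9,TRUE,TRUE,10000
2,P02,PRV1,2018-02-01,2018-02-08,I63.0,FALSE,TRUE,2000
3,P03,PRV2,2018-03-01,2018-03-06,I63.5,FALSE,FALSE,1000
4,P04,PRV2,2018-04-01,2018-04-04,I63.9,FALSE,FALSE,800
5,P05,PRV1,2019-11-15,2019-11-20,I63.9,FALSE,FALSE,1500
6,P06,PRV2,2018-06-10,2018-06-18,I63.4,FALSE,FALSE,1200
7,P07,PRV2,2018-05-01,2018-05-09,I63.9,FALSE,FALSE,900
8,P07,PRV2,2018-07-01,2018-07-05,I63.9,FALSE,FALSE,700
9,P08,PRV3,2018-08-01,2018-08-05,I63.9,FALSE,FALSE,1100
10,P09,PRV2,2018-09-01,2018-09-10,I63.9,FALSE,FALSE,950
11,P10,PRV1,2018-02-01,2018-02-01,I63.9,FALSE,FALSE,3000
12,P02,PRV1,2018-04-02,2018-04-06,J18.9,FALSE,FALSE,500
13,P03,PRV1,2018-05-30,2018-06-02,I69.3,FALSE,FALSE,600
14,P06,PRV2,2018-09-07,2018-09-09,N39.0,FALSE,FALSE,400
15,P09,PRV2,2017-12-15,2017-12-20,I63.9,FALSE,FALSE,850
16,P01,PRV1,2018-01-10,2018-01-15,I63.3,TRUE,FALSE,999
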