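patient_id,birth_date,sex,death_date
P01,1950-06-15,F,2018-03-25
P02,1940-01-01,M,
P03,1960-05-05,F,
P04,2005-03-01,M,
P05,1945-02-02,F,
P06,1935-07-07,M,2018-09-08
P07,1955-08-08,F,
P08,1965-09-09,M,
P09,1950-10-10,F,
P10,1948-11-11,M,2018-02-01
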