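case_id,onset_date,lat,lon,age,sex,esr,anc,crp,ggt_elevated,illness_day
T01,2010-01-01,32.75,-117.12,2.1,M,55,8200,7.2,0,3
T02,2010-01-02,32.77,-117.10,1.4,F,62,9100,9.5,0,2
T03,2010-01-02,32.70,-117.15,3.0,M,48,7000,5.1,1,4
T04,2010-01-03,32.80,-117.05,0.9,M,71,10400,11.0,0,5
T05,2010-01-09,33.05,-117.25,4.2,F,39,6100,4.4,0,6
T06,2010-01-15,32.62,-116.92,2.8,M,52,7900,6.8,0,2
T07,2010-01-15,32.64,-116.95,1.7,F,58,8800,8.1,0,3
T08,2010-01-16,32.61,-116.90,2.2,M,47,7300,5.9,1,4
T09,2010-01-17,32.66,-116.93,3.5,F,44,6800,5.0,0,7
T10,2010-01-18,32.63,-116.91,1.1,M,66,9700,10.2,0,3
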