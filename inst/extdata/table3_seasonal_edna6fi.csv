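site,date,score,printed_class
Ain,2015-10-15,0.75,Good
Ain,2015-12-15,0.74,Good
Ain,2016-02-15,0.76,Good
Ain,2016-04-15,0.72,Good
Ain,2016-06-15,0.74,Good
Ain,2016-08-15,0.74,Good
Jons,2015-10-15,0.68,Moderate
Jons,2015-12-15,0.69,Moderate
Jons,2016-02-15,0.68,Moderate
Jons,2016-04-15,0.65,Good
Jons,2016-06-15,0.69,Moderate
Jons,2016-08-15,0.73,Moderate
Tier,2015-10-15,0.66,Moderate
Tier,2015-12-15,0.68,Moderate
Tier,2016-02-15,0.59,Moderate
Tier,2016-04-15,0.60,Moderate
Tier,2016-06-15,0.64,Moderate
Tier,2016-08-15,0.64,Moderate
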