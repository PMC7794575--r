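date,pathway,c_mg_per_L,q_mm
2016-05-06,interflow,3.2,12.5
2016-06-21,interflow,5.1,20.0
2016-07-18,overland,11.4,62.0
2016-07-18,interflow,7.9,35.5
2016-07-23,overland,14.2,48.0
2016-08-02,interflow,6.3,18.0
2016-09-14,interflow,2.8,9.0
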