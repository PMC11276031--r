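species	gc1	gc2	gc3	gc_all	enc
ac	53.615	42.522	46.740	47.626	52.778
cr	51.832	41.442	41.977	45.084	52.283
dc	52.706	41.724	40.989	45.140	53.410
sm	55.834	42.535	60.650	53.006	50.498
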