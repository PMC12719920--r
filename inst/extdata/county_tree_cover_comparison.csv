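county,rap_pct,stepwise_pct
Garvin,23.64,22.54
Bryan,32.73,32.06
Marshall,35.08,35.63
Grady,17.43,18.68
Jefferson,14.19,16.16
Stephens,23.25,25.85
Pontotoc,34.47,37.9
Love,32.87,36.41
McClain,21.70,25.93
Carter,27.86,32.8
Murray,25.72,32.85
Johnston,32.24,40.96
Coal,41.46,50.35
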