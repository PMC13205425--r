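{"filters":[
{"m":9,"sigma":4.81270877,"theta":3.13540763,"lambda":7.47685794,"gamma":0.31561081,"psi":2.20899015},
{"m":8,"sigma":1.96396977,"theta":0.24860970,"lambda":2.96959010,"gamma":0.72105363,"psi":4.60142864},
{"m":13,"sigma":1.64780153,"theta":1.61016196,"lambda":2.83743557,"gamma":0.66358951,"psi":1.73766008},
{"m":15,"sigma":3.39179532,"theta":0.55921120,"lambda":1.16027452,"gamma":0.96851020,"psi":0.19780057}
],"metadata":{"source":"published median-fitness descriptor"}}
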