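{"filters":[
{"m":14,"sigma":2.87441456,"theta":0.64689645,"lambda":7.50065226,"gamma":0.48449909,"psi":0.16186625},
{"m":9,"sigma":4.60047050,"theta":2.76179466,"lambda":6.09504738,"gamma":0.27625496,"psi":1.01749004},
{"m":19,"sigma":2.91841521,"theta":1.58793182,"lambda":5.60334183,"gamma":0.17517662,"psi":3.61273987},
{"m":10,"sigma":1.54570447,"theta":1.59859262,"lambda":2.73917312,"gamma":0.98337168,"psi":1.01393177}
],"metadata":{"source":"published worst-fitness descriptor"}}
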