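{"filters":[
{"m":19,"sigma":3.12069459,"theta":1.51606866,"lambda":3.89019095,"gamma":0.65310207,"psi":4.58528896},
{"m":7,"sigma":3.02631751,"theta":0.45433475,"lambda":5.25153474,"gamma":0.83115052,"psi":2.04598812},
{"m":8,"sigma":4.91978266,"theta":1.01728566,"lambda":1.73791384,"gamma":0.62092611,"psi":2.98742533},
{"m":8,"sigma":2.76768679,"theta":0.29284487,"lambda":2.12407121,"gamma":0.50966019,"psi":4.89246233}
],"metadata":{"source":"published best-fitness descriptor"}}
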