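{
  "name": "dormand-prince-5(4)",
  "stages": 7,
  "c": ["0", "1/5", "3/10", "4/5", "8/9", "1", "1"],
  "a": [
    ["0", "0", "0", "0", "0", "0", "0"],
    ["1/5", "0", "0", "0", "0", "0", "0"],
    ["3/40", "9/40", "0", "0", "0", "0", "0"],
    ["44/45", "-56/15", "32/9", "0", "0", "0", "0"],
    ["19372/6561", "-25360/2187", "64448/6561", "-212/729", "0", "0", "0"],
    ["9017/3168", "-355/33", "46732/5247", "49/176", "-5103/18656", "0", "0"],
    ["35/384", "0", "500/1113", "125/192", "-2187/6784", "11/84", "0"]
  ],
  "b_high": ["35/384", "0", "500/1113", "125/192", "-2187/6784", "11/84", "0"],
  "b_low": ["5179/57600", "0", "7571/16695", "393/640", "-92097/339200", "187/2100", "1/40"],
  "order_high": 5,
  "order_low": 4
}
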