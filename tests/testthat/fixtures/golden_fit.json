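{
  "estimates": {
    "logq(1-2)": -1.29995883165288,
    "logq(1-3)": -5.50473012475856,
    "logq(1-4)": -2.94106768629918,
    "logq(2-1)": -1.66281519564472,
    "logq(2-3)": -4.38640830222413,
    "logq(2-4)": -2.41515367193014,
    "logq(3-4)": -1.29071267865858
  },
  "loglik": -478.263062090405
}
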