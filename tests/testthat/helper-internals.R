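# Internal engine entry points exercised directly by the gradient and
# determinism tests.
flatten_params <- dwisure:::flatten_params
unflatten_params <- dwisure:::unflatten_params
net_fwd <- dwisure:::net_fwd
net_bwd <- dwisure:::net_bwd
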