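key,value
fluid_crystallized_r,0.38
vermis_viii_cognition_r,0.26
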