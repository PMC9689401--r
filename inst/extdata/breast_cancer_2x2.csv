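histology,outcome,n
mixed,dead,26
mixed,alive,8
ductal,dead,38
ductal,alive,60
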