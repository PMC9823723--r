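child,mother,father
CV011,CV003,CV005
CV012,CV004,CV010
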