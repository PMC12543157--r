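procedure_code
0310010039
0310010055
0411010034
0411010026
0409060089
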