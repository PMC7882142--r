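((t05,t09),((t04,t12),(((t08,t11),t02),((t07,t10),t03))),(t06,t01));
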