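system_id,receptor,ligand,reference,cognate
5F2E,,,,TRUE
5V9U,,,,TRUE
6OIM,,,,TRUE
6P8X,,,,TRUE
6UT0,,,,TRUE
6T5B,,,,TRUE
6TAN,,,,TRUE
8DNI,,,,TRUE
8DNJ,,,,TRUE
8DNK,,,,TRUE
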