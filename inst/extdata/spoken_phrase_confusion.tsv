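phrase	Do you understand me	That's perfect	How are you	Good bye	I need help
Do you understand me	1332	12	19	11	8
That's perfect	10	1338	14	11	9
How are you	21	8	1331	12	10
Good bye	12	15	12	1337	6
I need help	7	12	14	7	1342
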