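variable,level,V,BV,B
grade,1,3,3,8
grade,2,27,44,44
grade,3,68,55,38
grade,Unknown,7,4,8
er,Positive,57,69,77
er,Negative,48,37,21
pr,Positive,39,53,59
pr,Negative,66,53,39
her2,Positive,31,22,15
her2,Negative,44,51,45
her2,Unknown,30,33,38
hormone_treatment,Yes,84,97,92
hormone_treatment,No,21,9,6
radiotherapy,Yes,79,84,82
radiotherapy,No,26,22,16
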