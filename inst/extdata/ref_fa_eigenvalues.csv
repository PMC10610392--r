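panel,component,eigenvalue
all_traits,1,3.76
all_traits,2,2.81
all_traits,3,2.70
all_traits,4,2.21
all_traits,5,2.06
all_traits,6,1.39
all_traits,7,1.21
all_traits,8,1.03
all_traits,9,0.736
all_traits,10,0.533
gy_panel,1,1.78
gy_panel,2,1.23
gy_panel,3,0.98
gy_panel,4,0.61
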