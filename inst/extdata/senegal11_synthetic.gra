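11
Dakar
1
Thies
Diourbel
4
Fatick Kaolack Louga Thies
Fatick
3
Diourbel Kaolack Thies
Kaolack
3
Diourbel Fatick Tambacounda
Kolda
2
Tambacounda Ziguinchor
Louga
4
Diourbel Matam Saint-Louis Thies
Matam
3
Louga Saint-Louis Tambacounda
Saint-Louis
2
Louga Matam
Tambacounda
3
Kaolack Kolda Matam
Thies
4
Dakar Diourbel Fatick Louga
Ziguinchor
1
Kolda
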