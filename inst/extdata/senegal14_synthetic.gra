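14
Dakar
1
Thies
Diourbel
5
Fatick Kaolack Kaffrine Louga Thies
Fatick
4
Diourbel Kaolack Kaffrine Thies
Kaolack
5
Diourbel Fatick Kaffrine Tambacounda Kedougou
Kaffrine
5
Diourbel Fatick Kaolack Tambacounda Kedougou
Kolda
4
Sedhiou Tambacounda Kedougou Ziguinchor
Sedhiou
4
Kolda Tambacounda Kedougou Ziguinchor
Louga
4
Diourbel Matam Saint-Louis Thies
Matam
4
Louga Saint-Louis Tambacounda Kedougou
Saint-Louis
2
Louga Matam
Tambacounda
6
Kaolack Kaffrine Kolda Sedhiou Matam Kedougou
Kedougou
6
Kaolack Kaffrine Kolda Sedhiou Matam Tambacounda
Thies
4
Dakar Diourbel Fatick Louga
Ziguinchor
2
Kolda Sedhiou
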