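CC(C)Cc1ccc(cc1)C(C)C(=O)O ibuprofen
Cc1cc(NS(=O)(=O)c2ccc(N)cc2)no1 sulfamethoxazole
CN1C(=O)CN=C(c2ccccc2)c2cc(Cl)ccc12 diazepam
C[C@]12C[C@H](O)[C@H]3[C@@H](CCC4=CC(=O)CC[C@]43C)[C@@H]1CC[C@@]2(O)C(=O)CO hydrocortisone
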