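id	sequence	structure	mfe	n_genome_hits
fix001	ACUCCUAGUAGAAUCUUGCACUCAUGUGUAACUGAGUGCAAGAUUCUACUACCGG	.....((((((((((((((((((..........))))))))))))))))))....	-18	1
fix002	CCUCCCUUCAUGACCCCUCGUGCGCUUGCCGUCGCACGAGGGCUCAUGAAGUCAA	.....((((((((.(((((((((..........))))))))).))))))))....	-17	1
fix003	AUCUAUGGACACACUAGUCGCCCACGACCCCUGGGGCGACUAGUGUGUCCACGCA	.....((((((((((((((((((..........))))))))))))))))))....	-18	1
fix004	GCGGUUCUGUAACUCCCCUUAGAGUGCAGCUAAUCUACAUGCGGUGAUUCUGAGUAG	.....((.(.(.(.((.(.(.(((..........)).)).).)).).).).))....	-12	1
fix005	ACCUCUUGUAACACUGAUGUCUCCGUAAUAGCCGGGAGACAUCAGUGUUACAAGGCC	.....(((((((((((((((((((..........)))))))))))))))))))....	-19	1
fix006	AACCCAAUCGUAUGUGAAUAAGACCCAUUUACGAAGGUCUUAUUGACAUACGAUUUACC	.....((((((((((.(((((((((..........))))))))).))))))))))....	-19	1
fix007	CUCGUUGCCCCCGAUGUACUGCUAUUUGCAUCAUUAGCAGAACAUCCGGGGCACCAC	.....((((((.(((((.((((((..........)))))).))))).))))))....	-17	1
fix008	CGUAGUGUUCAUUUCCGCACCUAUGACGUCAUUGGCAUUGGAGGGCAUAUCAUCAAGUU	.....((.(.((.(.(.(.((.(((..........)).))).).).).)).).))....	-13	1
fix009	UACGACCGCAUUUGAUCGGUGGAUCUUUGCACAAAUCCACGGAUCAUAUGCGGUCUA	.....((((((.(((((.((((((..........)))))).))))).))))))....	-17	1
fix010	ACAGCGUUUCCCGCCAUCUAGUGAUCGUGCAGCCCAUCACUUGAUGGCCGGAAACACAA	.....((((((.((((((.((((((..........)))))).)))))).))))))....	-18	1
fix011	UGACAUCUGAUGUCCAAAAACUGAGGAGCUUCUUACUCAGUUUUUGGACAUCAGAAGCC	.....((((((((((((((((((((..........))))))))))))))))))))....	-20	1
fix012	ACAGUUCUCCUAAAGUUAGUGGUACGGAUGCCCGUACCAGUUACAUAACGUGAAUAC	.....((.(.(.(.((.(.(.(((..........)).)).).)).).).).))....	-12	1
fix013	GGCCUUCGAUUGGCCAGUGAACUGCUAAACACGAGUUCAGUGGCGAAUCGACUUC	.....((((((.((((.((((((..........)))))).)))).))))))....	-16	1
fix014	GACGGCUAGCAUUACAUAAUGUUUGCUCAUCAUAACAUUAUGAAAUGCUAGUCUC	.....((((((((.(((((((((..........))))))))).))))))))....	-17	1
fix015	AUAUGCUUUAUCGUGCGAAGCUGGUGGGGGAGGGCCAGCUACGCACCAUAAAGACCC	.....((((((.(((((.((((((..........)))))).))))).))))))....	-6.8	1
fix016	ACUAAUGGUUAGGUAGCAUACAUGUAUAAAAUGAUCGAAGGUUCGUUAGCAGUUU	.....((.(.(.(.(.(.(.(((..........)).)).).).).).).))....	-11	1
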