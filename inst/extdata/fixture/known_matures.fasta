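>ath-miR002
CTTCATGACCCCTCGTGCGC
>ath-miR006
AATCGTATGTGAATAAGACCCA
>ath-miR010
GTTTCCCGCCATCTAGTGATCG
>ath-miR014
CTAGCATTACATAATGTTTG
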