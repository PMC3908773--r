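name	length	aa_sequence	printed_hp
4BP2	123	ALWQFNGMIKCKIPSSEPLLDFNNYGCYCGLGGSGTPVDDLDRCCQTHDNCYKQAKKLDSCKVLVDNPYTNNYSYSCSNNEITCSSENNACEAFICNCDRNAAICFSKVPYNKEHKNLDKKNC	PHHPHPPHHPHPHPPPPPHHPHPPHPHHHPHPPPPPPHPPHPPHHPPPPPHHPPPPPHPPHPHHHPPPHPPPHPHPHPPPPHPHPPPPPPHPPHHHPHPPPPPHHHPPHPHPPPPPPHPPPPH
2AAS	124	KETAAAKFERQHMDSSTSAASSSNYCNQMMKSRNLTKDRCKPVNTFVHESLADVQAVCSQKNVACKNGQTNCYQSYSTMSITDCRETGSSKYPNCAYKTTQANKHIIVACEGNPYVPVHFDASV	PPPPPPPHPPPPHPPPPPPPPPPPHHPPHHPPPPHPPPPHPPHPPHHPPPHPPHPPHHPPPPHPHPPPPPPHHPPHPPHPHPPHPPPPPPPHPPHPHPPPPPPPPHHHPHPPPPHHPHPHPPPH
5LYZ	129	KVFGRCELAAAMKRHGLDNYRGYSLGNWVCAAKFESNFNTQATNRNTDGSTDYGILQINSRWWCNDGRTPGSRNLCNIPCSALLSSDITASVNCAKKIVSDGNGMNAWVAWRNRCKGTDVQAWIRGCRL	PHHPPHPHPPPHPPPPHPPHPPHPHPPHHHPPPHPPPHPPPPPPPPPPPPPPHPHHPHPPPHHHPPPPPPPPPPHHPHPHPPHHPPPHPPPHPHPPPHHPPPPPHPPHHPHPPPHPPPPHPPHHPPHPH
9WGA	170	RCGEQGSNMECPNNLCCSQYGYCGMGGDYCGKGCQNGACWTSKRCGSQAGGATCPNNHCCSQYGHCGFGAEYCGAGCQGGPCRADIKCGSQSGGKLCPNNLCCSQWGFCGLGSEFCGGGCQSGACSTDKPCGKDAGGRVCTNNYCCSKWGSCGIGPGYCGAGCQSGGCDA	PHPPPPPPHPHPPPHHHPPHPHHPHPPPHHPPPHPPPPHHPPPPHPPPPPPPPHPPPPHHPPHPPHPHPPPHHPPPHPPPPHPPPHPHPPPPPPPHHPPPHHHPPHPHHPHPPPHHPPPHPPPPHPPPPPHPPPPPPPHHPPPHHHPPHPPHPHPPPHHPPPHPPPPHPP
1RBP	174	ERDCRVSSFRVKENFDKARFSGTWYAMAKKDPEGLFLQDNIVAEFSVDETGQMSATAKGRVRLLNNWDVCADMVGTFTDTEDPAKFKMKYWGVASFLQKGNDDHWIVDTDYDTYAVQYSCRLLNLDGTCADSYSFVFSRDPNGLPPEAQKIVRQRQEELCLARQYRLIVHNGYC	PPPHPHPPHPHPPPHPPPPHPPPHHPHPPPPPPPHHHPPPHHPPHPHPPPPPHPPPPPPPHPHHPPHPHHPPHHPPHPPPPPPPPHPHPHHPHPPHHPPPPPPPHHHPPPHPPHPHPHPHPHHPHPPPHPPPHPHHHPPPPPPHPPPPPPHHPPPPPPHHHPPPHPHHHPPPHH
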