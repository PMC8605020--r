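>merA_ref
IVEECSEHCILKQKCYCFWNNEITEELCDCTKIDPIHFSPDFWHMSQACCQCKEHKKWEHHRVYHAVQKNWMVIEFGAQDHNTWVCHPDMDCQRHANHTNHYNIKHWKAACHCHVHLGKGDNIGFFHDNSSMGTQCWNSACIKQGFQIVECVGTTTKINNHTRAPSQPICIKRFWPNHYVPEMIWGHQARPCDAIGHQDDSFLRMENFDPLSSDQFPKWIDISGERLVGMDAWADDKPMSDPRLNQMPTARPPQIFSIKKRNSHRIKFVPMWQPAFTMSMKEQKESETQHPNHDRNKYLTYWFGPHWYKRQNLGNIGPRLGYKLECAMSMVWCCENLRKAMNEHTRGPTGQWNFPSNWMFLLLIFETVTINFTPTDLVFASSSYPHKDEGAICHMDQWPCGGWACWTWVPHGPHPHIIFHCPWDTWNVMQLVSNTDWIEYTQISLNTMKGGWWRLGIKRGLPCYTRWENAKVNFYAVRQPCLRHQNKWGLLDPSMGQDYMKHDGEKGCTHIHECGWNMVLKCFFKWKLTRRQPRNFIRQQPEALSMLLQVNGYMACWCCYY
>merA_seed2
IVEECSEHCHLKQKCYCFWNNEITEELCDCTKIDPIHFSPDFWHMSQACCFCKEHKKWEHHRVYDAWEKNWMVIEFGAQDHNTWVCHPDMDCLRHANHTSHYNIKHWKAACHCHVHLGKGRNIGFFHDNSSMGTQCWNSACIKQGFQIVECVGTTTKINNHTRAPSQPICIKRFWPNHYVPEMIHGHQARPCDAIGHQDDSFLRMENFDPLSSDQFPKWIDISGERLVGMQAWAVDKPMKDPRLNQMPTAGPPVIFSIKKRNSHRIWFVPMWQPAFTMSMKEQKESETQHPNHDQNKYLTYWFGPHWYKRQNLGNIGPRLGYKLECACSMVWCCENLRKAMNEHTQGPTGQWNFPSNWMFLLLIFETETINFTPTDLSFASSSYPHKDEGAICHMDQWPCGGWACWTWVPHGWHPHIIFHCPWDTWNVMQLVSNTDWIEYTQISLNTMKGGWWRLGIKRGLNSYTRWENAKVNFYAVRQPCLRHQNKWGLLNPSMEQDYMKHDGEKGCTHIHECGWNMVLKCFFKWKLTRRQPRNFIRQQPEALSMPLQVNGYMACWCCYY
>merA_seed3
IVEECSEHCILKIKCYCFWNNEITEELCDCTKIDPIHFSPDFWHMSQACCQCKEHMKWEHHRVYHAVQKQWMVIEFGAQDHNTWVCHPDVDCQRHANHTNHANIKHWKAACHWHVHLGKGDNILFFHDNSSMGTQCWNSACIKQGFQIVEEVGTTTKINPHTRAPSQPICIKRFWPNHYVPEMIWGHQWRPCDAIGKQDDSFLRMENFDPLSSDQFPKWIDISGERLVGMDAWADDKPMSDPELNQMPTARPPQIFSIKKRNSHRITFVPMWQPAFTMSMKEQKESETQHPNHDRNKYLTYWFGPHWYKRQNLGNIGPRLGYKLECAMSMVWCCENLSKACNEHTRGPTGQWNFSSNWMPLLDIFETMTINFTPTDLVFASSSYPHKDDGAICHMDQWPCGGWACWTWVPHGPHWHIIFHCPWDTWNVMQLVPNTDWIEYTQISLNTMKGGWWRLGIKRGLPCYTRWENAKVNFYAVRQPCLRHQNKWGLLDSSMGQDYMKHDGEKGCTHIPECGWNMVLECFFKWKLTERQPRNFIRQQPEALSMLLQVNGYMACWCCYY
>merA_seed4
IVEKCSEHCILKQKCYCFVNNEITEELCDCTKIDPICFSPDFWHMSQACCQCKEHKKWEHHRVYHAVQKFWMVIEFGAQDHNTWVCHPDMDCQRHANHTNHYNMKHWKAACHCHVHLGKGFNIGFFHDNSSMGTQCWNSICIKQGFQIVECVGTTTEINNHTRAPSQPICIKRFWPNHYVPEMIWGHQARPCDAIGPQDDSFLRMENFDPLSSDQFPKWIDISFERLVGMDAWADDKPMIDPRLNQMPTARPPQIFSIKKRNSHRIKFVPMWQPAFTMSMMEQKESETQHPNHDRNKYYTYWFGPHWYKRWNLGNIGPRLGYKLECAMHMVWCCENLRKAMNENTRGPTGQWNFPSNWMFLVLIFETVTINFTPTDLVFASSSYPHKDEGAICHMDQMPCGGWACWTWVPHGPHPHIIFHCPWDTWNVMQLVSNTDWIEYTQISLNTMKGGWWRLGILRGLPCYTRWENAKVNFYAVRQPCLRHQNKWGLLDPSMGQDYMKHDGEKGCTHIHECGWNMVLKCFFKWKLTRRQPRNFIRQQPEALSMLYIVNGYMACWCCYY
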