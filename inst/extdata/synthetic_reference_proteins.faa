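>hgcA_ref synthetic reference
TNGCCVKWHPAQLWSGRITSNWSPQQARYCKCDKRVISKNRCCPDGFNYDITENESVDTRMVVHRYAWAKHETQWGEMRHLPDPNCGNCKMGNVWCAAGKPPRTDRCAVAAWYTANLPHAIHILSNDSWPKPPLGTNYINCGHKQGSEHIIHYKTHIIKSQCYEPASVMAAEPMNIKVYPHHLFCIRYVTARIFHKFAWQPKWRCQATVDHEAHHLVTLVAQSRAWFGWCFQELLTECFKHVLMWQGSVICWYYSVGHMRSFRGMLIGLGNRKEHMENWYWADPHFKKSGFDPMAKIYLYCVPARFNEYVGVVFREAIRSEFMIEMHENESYFQIEMKKA
>hgcB_ref synthetic reference
EYAILWYRDGKYSTGDVRRIQYPQNFMMYGFCMCQMCRWCVERSKAALEETTGVRFDAVYNKCPVCIWCHFPRNFALWLYTLTAICRAKWVQTLA
>merA_ref synthetic reference
IVEECSEHCILKQKCYCFWNNEITEELCDCTKIDPIHFSPDFWHMSQACCQCKEHKKWEHHRVYHAVQKNWMVIEFGAQDHNTWVCHPDMDCQRHANHTNHYNIKHWKAACHCHVHLGKGDNIGFFHDNSSMGTQCWNSACIKQGFQIVECVGTTTKINNHTRAPSQPICIKRFWPNHYVPEMIWGHQARPCDAIGHQDDSFLRMENFDPLSSDQFPKWIDISGERLVGMDAWADDKPMSDPRLNQMPTARPPQIFSIKKRNSHRIKFVPMWQPAFTMSMKEQKESETQHPNHDRNKYLTYWFGPHWYKRQNLGNIGPRLGYKLECAMSMVWCCENLRKAMNEHTRGPTGQWNFPSNWMFLLLIFETVTINFTPTDLVFASSSYPHKDEGAICHMDQWPCGGWACWTWVPHGPHPHIIFHCPWDTWNVMQLVSNTDWIEYTQISLNTMKGGWWRLGIKRGLPCYTRWENAKVNFYAVRQPCLRHQNKWGLLDPSMGQDYMKHDGEKGCTHIHECGWNMVLKCFFKWKLTRRQPRNFIRQQPEALSMLLQVNGYMACWCCYY
>merB_ref synthetic reference
MYVSTYVWGPKRHGMPWCNRYTPSLEMIASMKTETRQQMKIIYFDSIYTDWFNVTMSIDEEIYFRCGFYKHTSYGHGAALMFAENWIEMGNEHHKCWNDGHKVCGHKHACACYFDLCVLSYVIQKNVRTWLYIYRDVHIICCPELVKPMYLIMETSCMCHYYSKGDQFPASEIVAIKEIKGIRPKVNSVNKPAPTFKDFVYGFTHKRKCNKK
>rpoB_ref synthetic reference
QNSMAWPHMDELCRDWWLYTVYRASGMRPGENHDLRKAPGNLKPVHFRHRNIDMLPHVASTWQCTDKKMSTTMEANIWCGETSWFLNPYRRKYLGPVDYPGWWRHFSPDFQDRNHTKFEHSPSVCLIPYMLCDIPHEAAFNDQMDDHGPTWTKVRIQWATAKTDITDQFTHCAHHTFTWTKRLVINVGPEGNKPVHRRVWSNLRDMFNPRWHPPPYCDHNSCETFEVCFELRYSRRLRWQQHDAADVRDGQCFWHLHVRMWVPHITTLILYAPYIRFEHAMVNCTSVTKFGRMFTINIHGFHTQVMISYPFAKTVNECPSGPSPWHIDKMRILDPIFLPVRDCTETCVQHKCQLICNHNTEKPVMLHRGANIWKIKHWGKAAFVQGLDHMFVDLMKMVDV
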