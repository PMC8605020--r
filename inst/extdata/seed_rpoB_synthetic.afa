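>rpoB_ref
QNSMAWPHMDELCRDWWLYTVYRASGMRPGENHDLRKAPGNLKPVHFRHRNIDMLPHVASTWQCTDKKMSTTMEANIWCGETSWFLNPYRRKYLGPVDYPGWWRHFSPDFQDRNHTKFEHSPSVCLIPYMLCDIPHEAAFNDQMDDHGPTWTKVRIQWATAKTDITDQFTHCAHHTFTWTKRLVINVGPEGNKPVHRRVWSNLRDMFNPRWHPPPYCDHNSCETFEVCFELRYSRRLRWQQHDAADVRDGQCFWHLHVRMWVPHITTLILYAPYIRFEHAMVNCTSVTKFGRMFTINIHGFHTQVMISYPFAKTVNECPSGPSPWHIDKMRILDPIFLPVRDCTETCVQHKCQLICNHNTEKPVMLHRGANIWKIKHWGKAAFVQGLDHMFVDLMKMVDV
>rpoB_seed2
QNSMAWPHMDELCRDWWLYTVYRASGMKPGENHDLRKAPGNLKTVHFRHRLIDMLPHVASSWQCTDKRMSTTMEANIWCGETSWFLNPYRRKYLGPVDYPGWWRHFSPDTQDRNHTKFEHSPSVCLIPYMLCDIPHEAAFNDQMDDHGPTWTKVRIQLATAKTDITDQFTHCAHHTFTWTKRLVINVGPEGNKPVHRRVWSNLRDMFNPRWHPPVYCDHNSCKTFEVCFMLRYSRRLRWQQHDAALVRDGQYFWVLNVRMWVPHITTLILYAPLIRFAHATVNCTSVTKFGRMFTINIFGFHTQVMISYPFAKTVNECPSGPSPWHIDKMRILDPAFLPVRDCTETCVQHKCQLICNHNTEKPVMLHRGANWWKIKHWGKAAFVQGLDHMFVDLMKMVDV
>rpoB_seed3
QNSMAWPHMDELCRDWWLYTVYRASGMRPGENHDLRKAPGNLKPVHFRHRNIAMLPHVASTWQCTDKKMSTTMEANIWCGETSWFLNPYRRKYLGNVDYPGWWRHFSGDFQDRNHTNFEHSPSVCLIPYMLCDIPHEAVFNDQMDDHGPTWTKVRIQWATAKTDITDQFTHCAHHTFCWTKRLVINVGPEGNKPVHRRVWSNLRDMFNPRWHPPPYCDHNSCNTFEVCFEVRYSRRLRWQQHDAADVRDGQCFWTLHVRMWVVHITTLILYAPYIRFEHVMVNCTSVTKFGRMRTINIHGFHTEVMISYPFAKTVNECDSGPSVWHISKMRILDPIFLCVRDCTETCVQHTCQLICNHNTEKPVMPHRGANIWKIKHWGGAAFVQGLDHMFVDLMKMVDV
>rpoB_seed4
QNSMIWPHMDELCRDWWLYTVYRASGMRPGENHDLRKAPGNLKPVHFRHRNIDMLPHVASTWQCTIKKMSTTMEANIWCGETSWFLNPYRRKYLGPVDYPGWWRHFSPDFQDRNHDKFEHSPSVCLIPYMLCLIPHEAAFNDQMDYHGPTGKKVRIQWRTAKTDITDQFTHCAHHTFTWTKRAVINVGPEGNKPVHRRVWSNLYDMFGPRWHPPPYCDHNSCETFEVCFELRYSRRLRWQQHDAADVRDGQCFWHLHVRMWVPHITTLILYAPYIRFEHAMVNCTSVTKFGFMFTINIHGFHTQYMISYEFAKTVNECPSPDSPWVIDKMRILDPIFLSVRDCTETCVQHKCQLICNHNTEKHVMLHRGANIDKIKHWGKAAFVQGLDHMFVDLMKMVDV
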