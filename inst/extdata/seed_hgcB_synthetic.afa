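>hgcB_ref
EYAILWYRDGKYSTGDVRRIQYPQNFMMYGFCMCQMCRWCVERSKAALEETTGVRFDAVYNKCPVCIWCHFPRNFALWLYTLTAICRAKWVQTLA
>hgcB_seed2
EYAILWYRDGKKSTGDVRRIQYPQNIMMYDFCMCQMCRWCVERSKAALEETTGVRFDAAYNKCPVCIWCHFPRNFALWLYTLTTICRAKWVQTLA
>hgcB_seed3
EYAILWYRDGKYSTGDVRRIQTPQNFMMYGFCMCQMCRWCVERSKAALEETTGVRFDACYNKCPVCIWCHFPRNFALWLYTLTAICRAKWVQTLA
>hgcB_seed4
EYAIHWYRDGKYSTGDVRRIQYPQNFMMYGMCMCQMCRWCVERSKAALEETTGVRFDAVYNKCPVCIWCHTPRNFALWLYTLTAICRAKWVQTLA
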