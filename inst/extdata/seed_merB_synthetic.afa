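>merB_ref
MYVSTYVWGPKRHGMPWCNRYTPSLEMIASMKTETRQQMKIIYFDSIYTDWFNVTMSIDEEIYFRCGFYKHTSYGHGAALMFAENWIEMGNEHHKCWNDGHKVCGHKHACACYFDLCVLSYVIQKNVRTWLYIYRDVHIICCPELVKPMYLIMETSCMCHYYSKGDQFPASEIVAIKEIKGIRPKVNSVNKPAPTFKDFVYGFTHKRKCNKK
>merB_seed2
MYVSTLVWGPKRHGMPWCNRYTPSLEMIASMKTETRDQMKIIYFDSIYTDWANVTMSIDEEIYGRCGFYKHTRYGHGAALMFAENHIEMGNEHRKCWNDGHKVCGHKHACACYFDLCVLSYVIQKNVREMLYIYRDVTIICCPELVKPMYLIMETSCMCHYYSKGDQFPASEIVAIKEIKGIFPKVNSVNKFAPTFKDFVYGFTHKRKCNKK
>merB_seed3
MYVSTYVWGPKRHGMPWCNRYTPSLEMIASMKTETRQQMKIIYFDSGYTDWFNVTHSIMEEIEFTCGFYKHTSYGHGAALMKAENWIEMGNEHHKCWNDGHKVCGSKHCCACYKDLCVLSYVIQKNVRTWLYIYQDVHIICCPELVKPMYLIMETSCMCHYYSKGDQFPASEIVAIKEIKGIRPKVNSVNKPAPTFKDFVYGFTHKRKCNKK
>merB_seed4
MYVSTYVWGPKYHGMPWCNRYTPSLEMIASMKTETRQQMKIIYFDSIYTDSFRVTMSIDEEIYFRCGFYKHTSYGHKAALMFAENWIEMGNEHHKCWNDGHKVCGHKHACACYFDLCVLSYVIQKNVCTWLYIYRDVHIICCPELVKPMYLGMETSCMCHYYSKGDQFPASEIVAIAEIKGIRPKVNSVNKPAHTFKDFVYGFTHKRKCNKK
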