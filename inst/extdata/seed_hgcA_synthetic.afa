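>hgcA_ref
TNGCCVKWHPAQLWSGRITSNWSPQQARYCKCDKRVISKNRCCPDGFNYDITENESVDTRMVVHRYAWAKHETQWGEMRHLPDPNCGNCKMGNVWCAAGKPPRTDRCAVAAWYTANLPHAIHILSNDSWPKPPLGTNYINCGHKQGSEHIIHYKTHIIKSQCYEPASVMAAEPMNIKVYPHHLFCIRYVTARIFHKFAWQPKWRCQATVDHEAHHLVTLVAQSRAWFGWCFQELLTECFKHVLMWQGSVICWYYSVGHMRSFRGMLIGLGNRKEHMENWYWADPHFKKSGFDPMAKIYLYCVPARFNEYVGVVFREAIRSEFMIEMHENESYFQIEMKKA
>hgcA_seed2
TNGLCVKWHQAQLWSGRITSNWSPQQARYCKCDKRVISKNRCCPDGFNYDITENESVDTRMVVHRYAWAKTETQWGEYRHLPDPNCGNCKMGNVWCAAGKPPRTERCAVAAWYTANLPHAIKILSNDSWPKNPLGTNYINCGHKQGSENIIHYKTHIIKSQCTEPASVMAAEPMNIKVYPHHLFCIRYVYARIYHKFAWQPKWRCQATVDHEWHHTVTLVAQSRAWFGWCFQELLTECFKHVLMWPGSVICWYYSVGHMRSFRGMLIGLGNRKEHMEMWYWADPHFKKSGFDPMAKIYLYMVPARFNEYVGVVFREAIRSEFMIEMHENESYFQIEMKMA
>hgcA_seed3
TNGCCVKWHPAQLWSGRITSNWSPQQARYCKCDKRVISKARCCPQGFNYDITANESVDTRMVVHRYAWAKHETQWGEMRHLPDPNCGNCKMGNVWCAAGKPPRTDRCAVCAWYTTNLPHAIHILDNDSWPKPPLGTNYINCGHKQGSEHIIHYKTHIIKSQCYEPANVMAAEPMNIKVYPHHLFCIRYVTARIFHTFAWQPKWRCQATVDHEAHHLVQLVAASRAWFGWCFQELLTECFKWVLMWQGSVICWYYSVGHMRSFRGMLIGLGNRKEHMENWYWKDPHFKKSGFDPMAKIYLYCVPARFNEYVGVVFREAIRSEFMIEMHENESYQQIEMKKA
>hgcA_seed4
TNGCCVKWHPAQLWSGCITSNWSPQQARYCKCDKRVISKNRCCPDGFHYDITENESVDTRMVVHRYAWIKHETQWGEMRHLPDPNCGNCDMGNVWCAAGKPNRTFRCLVAAWYTANLPHAIHILHNDSWPVPPLGTNAINCGHKQGSEHIIHYKTHIIKSQCYEPASVMAAEPMNIKVYHHHLFCIRYVTARIFHKFAWQPKWRCQATVDFEAHHLVTLVHQSRVWFGWCFQELLTECFKHVLMWQGSVICWYESVGHMRSFRGMHIGLGNRKTHMENWYWADPHFKKSHFDPMAKIYLKCVPARFNEYGGVVFREAIRSEFMIEMHENESYFQIEMKKA
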