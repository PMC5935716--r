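LOCUS       SYNMITO01               1260 bp    DNA     circular SYN 01-JAN-2020
DEFINITION  Synthetic miniature mitochondrial genome for reader tests.
ACCESSION   SYNMITO01
FEATURES             Location/Qualifiers
     source          1..1260
                     /organism="synthetic construct"
     tRNA            1..66
                     /gene="trnW"
                     /product="tRNA-Trp"
     CDS             complement(67..366)
                     /gene="nad2"
                     /product="NADH dehydrogenase subunit 2"
     gene            complement(67..366)
                     /gene="nad2"
     tRNA            complement(370..435)
                     /gene="trnQ"
     rRNA            complement(440..940)
                     /gene="rrnS"
     CDS             945..1130
                     /gene="atp8"
     D-loop          1131..1260
ORIGIN
//
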