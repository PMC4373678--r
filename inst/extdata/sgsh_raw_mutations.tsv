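label	class
Ala30Pro	missense
Gly33Arg	missense
Tyr40Asn	missense
Tyr40Ser	missense
Asn42Lys	missense
Ala44Thr	missense
Leu59Phe	missense
Ser66Trp	missense
Ser68Arg	missense
Thr79Pro	missense
His84Tyr	missense
His84Arg	missense
Gln85Arg	missense
Met88Thr	missense
Gly90Arg	missense
Ser106Arg	missense
Thr118Pro	missense
Gly122Arg	missense
Pro128Leu	missense
Val131Met	missense
Thr139Met	missense
Leu146Pro	missense
Arg150Gln	missense
Arg150Trp	missense
Arg150Gly	missense
Leu163Pro	missense
Asp179Asn	missense
Pro180Leu	missense
Arg182Cys	missense
Gly191Arg	missense
Phe193Leu	missense
Arg206Pro	missense
Phe225Leu	missense
Pro227Arg	missense
Ala234Gly	missense
Asp235Asn	missense
Asp235Val	missense
Arg245His	missense
Arg245Met	missense
Asp247His	missense
Asp247Tyr	missense
Gly251Ala	missense
Thr271Met	missense
Gly275Arg	missense
Arg282Lys	missense
Tyr286Ser	missense
Pro288Ser	missense
Pro288Leu	missense
Glu292Lys	missense
Pro293Ser	missense
Pro293Thr	missense
Ser298Pro	missense
Glu300Val	missense
Arg304Leu	missense
Gln307Pro	missense
Ala311Asp	missense
Asp317His	missense
Thr321Ala	missense
Ile322Ser	missense
Ser347Phe	missense
Ser347Tyr	missense
Ala354Pro	missense
Glu355Lys	missense
Ser364Arg	missense
Glu369Lys	missense
Tyr374His	missense
Met376Arg	missense
Arg377Cys	missense
Arg377His	missense
Arg377Leu	missense
Gln380Arg	missense
Leu386Arg	missense
Asn389Lys	missense
Asn389Ser	missense
Leu411Arg	missense
Thr415Pro	missense
Thr421Arg	missense
Arg433Gln	missense
Arg433Trp	missense
Asp440Gly	missense
Asp444Gly	missense
Glu447Lys	missense
Arg456His	missense
Gln472His	missense
Asp477Glu	missense
Val486Phe	missense
Val226Ala	missense
Trp146Ter	nonsense
c.1080delC	frameshift
c.1213+1G>A	splice
c.1-24del	other
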