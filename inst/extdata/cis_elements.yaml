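# Starter cis-element dictionary: 30 canonical plant promoter elements,
# consensus IUPAC patterns, five functional classes.
ABRE:
  pattern: ACGTG
  class: hormone
ABRE3a:
  pattern: TACGTG
  class: hormone
ABRE4:
  pattern: CACGTA
  class: hormone
CGTCA-motif:
  pattern: CGTCA
  class: hormone
TGACG-motif:
  pattern: TGACG
  class: hormone
TCA-element:
  pattern: CCATCTTTTT
  class: hormone
GARE-motif:
  pattern: TCTGTTG
  class: hormone
P-box:
  pattern: CCTTTTG
  class: hormone
TATC-box:
  pattern: TATCCCA
  class: hormone
AuxRR-core:
  pattern: GGTCCAT
  class: hormone
TGA-element:
  pattern: AACGAC
  class: hormone
ERE:
  pattern: ATTTTAAA
  class: hormone
LTR:
  pattern: CCGAAA
  class: stress
MBS:
  pattern: CAACTG
  class: stress
TC-rich-repeats:
  pattern: ATTCTCTAAC
  class: stress
ARE:
  pattern: AAACCA
  class: stress
W-box:
  pattern: TTGACC
  class: stress
WUN-motif:
  pattern: AAATTTCCT
  class: stress
DRE-core:
  pattern: GCCGAC
  class: stress
STRE:
  pattern: AGGGG
  class: stress
G-box:
  pattern: CACGTG
  class: light
Box-4:
  pattern: ATTAAT
  class: light
GT1-motif:
  pattern: GGTTAA
  class: light
TCT-motif:
  pattern: TCTTAC
  class: light
GATA-motif:
  pattern: AAGGATAAGG
  class: light
I-box:
  pattern: GATAAGGCG
  class: light
MRE:
  pattern: AACCTAA
  class: light
CAT-box:
  pattern: GCCACT
  class: development
O2-site:
  pattern: GATGACATGG
  class: development
circadian:
  pattern: CAAAGATATC
  class: development
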