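>BsArgR_interdomain synthetic record carrying the Bs-group alpha4 triad segment
LPADQRFNPLSKLKRALMDA
>MtArgR_interdomain synthetic record carrying the Mt-group alpha4 triad segment
VPEDGSPVRGVSGGTDRMARLLGELLV
>EcArgR_alpha5 synthetic record carrying an Ec-group binding-site motif
NLVLVQTLIARGADKQAAIS
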