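>seed01
MAEALVGGALLSALLQVLFDRLASPEVVDFIRGKKLDEKLLKKLKTTLLSLQAVLNDAEQ
KQ
>seed02
MAEALVGGALLGALLQVLFDRLASPEVVDGIRGKKLDGKILKKLKTTPLSLAAVLNDAEQ
KQ
>seed03
MAEAFVPGALLSALLDVLFDRLASPEVVDFIRGKKLDEHLLMKLKTTLNSLQAVLNDAEQ
KQ
>seed04
HAEANVGGALLSALLQVLFKRLASPEVVDQIRGKKLDEKLPKKLKTTLLSLQAVVNDAEQ
KQ
>seed05
MAEALVGGALLSALLVVLFDRLASCEVVDFIRGKKLLEKLLKKLKTPLLSKQAVLNDYEQ
KQ
>seed06
MAEALVDGARLSALPQVLFDRLASPEVVDPIRGKKLDEKLLKKLKTTLLWLQMVLNDAEQ
KQ
>seed07
MAEALVGGALLSAMEQVLFDRLASPEVIDFIMGKKLDEKLLKKLKTTLLILQAVLNAAEQ
KQ
>seed08
MAETLVGGALLSALLKVLFDRGASPEVVDFIRGKKLVEKLLKKLKTTNLSLQAVTNDAEQ
KQ
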