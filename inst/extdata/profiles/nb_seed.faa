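>seed01
VGLEGIVKEVLEKLDSPELRVIPIVGMGGIGKTTLAQLVYNDPRVQEHFDLKAWVCVSDD
FDVKRLTKEIIESATGKACELNNLDALQVKLKEILQGKRFLIVLDDVWNEDRDKWEALRT
PLNAGAPGSKIIVTTRNESVALMMGTVPPYHLSGLSEDDCWSLFKQRAFGPNEEEQVELE
EIGKEIVKKCGGLPLAAKTL
>seed02
VGLEGIVKEVLEKLDPPELRNIPIVGMGGIGKTTLAQLVYNDPRTHEHFGLKAWVCVSDH
FDVKRLTKEIIRSATGKPFELNNLIALQVKLKEILQGKRFEIVLDDVWNEDRDYMEAYKT
PLNAPAPGSKIIVTTRNESVALCMGTVPPYHLSGLSEDDCWSLFKQRAFGPNEEEQMELE
EIGKEIVKWCGGLPLAAKTP
>seed03
VGLEGIVKEVLEKNASPEDSVIPIVGMGHIGKTTYAQLVYNDPWVQWHFDLFAWVAVSDD
CDVKRLTKEIIESATGKACELNNLDALQVKLKEILQGKRGLIVLKDVWNEDRDKWEALRT
PLNAGAPGSKHIVRTRNECVALMMNTVPPYHLSGLSEDGCWSLFKQRAFGPNEEEQYELE
EIGSEIVKKCGGLPLAAKTL
>seed04
VGLEGIPKEQLEKLDLWELQLIPIVGMGGIGKNTLAQLVYNDPRVQEHFDLKAWVCVSDD
FDVKRLPKEIIESATGKACELNNLDALQVLLKEIGQHLRFLIVLDDVWNECRDKWEALRT
PLNQGWPGSKIIVTTRNESVALMMGTVPPYHLSGLSEDDCNSLFKQRAFGPNEEEQVELE
EIGYEIVCKCGGLPLTPKTL
>seed05
VGLEGIVKEFLEKLDLPELRVIPIVGMGGIGKKICAQLVYNDPRLQEHFDLKAWVCVIDD
FDVKRHTKEIIESATGKACELTNLDALQVKLKEILQGKRFLIVLDDVWNEDRDKWEPLRT
PLNAGAPGSKNIPTTRNEEVALMMGMVPPEHLSGLSEDDCWSLGKQRAFGPNEEQQVELE
EIGKEIVQKTGGLPLKAKTL
>seed06
VGLEGIVDEVLEVLDQPELRVIPIVGMGGIGKTTLAQLVDNDPRVQEHFDLKAWVCVSDD
FDVKRLTKEINECATGKACELNNMDALQVALKEILQGKRFLIVLDDVWNFNRVKWEIVRT
PLNAKATGSKIIVTTRAESVAKMMKTVPPYHLSGNSEDDCWSLFKQRAFGPNEEEQVELE
EIGKEIVDKCGGLPLAAKTL
>seed07
VGYMGIVKEHLEKLFSPELRHIPIVGMYGANKFTLAQLVYNDPRVQECFDLKAWVCVSDD
FDVGRLTKEIIESATGKACELNGLDALQVKLKEILQGKRFLIVLDDVWNEDDDKWRANRT
PLNAIAPGSKIIVTTRNESVALMMGTVPPYHCSGLSEDDCWSLYKQRAFGPNEEEQVEEE
EIGKEIVKKCGGLRLAAKTL
>seed08
VGLEGIVKEVLEKLDSPELRVIPIVGMGGIGKTTLTQLVTNDPRVQEHFDTKAWVCVYDD
FDVKRLTMEIIESALGKACELNGPEALQVKLKEILQGKRFLIVLDDFWNEDRDKAEALRI
PLNAGAPFSKIIETTRNESVSLMCGTVPPYDLSGLSEDDCWSLFIQRAFGPNEFEQVELE
EIGKQIVKKCGGLPLAAKTL
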