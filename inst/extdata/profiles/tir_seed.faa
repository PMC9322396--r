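>seed01
YDVFLSFRGEDTRKTFTSHLYEALKDRGIHTFIDDEELRRGDEISPALLKAIEESRIAII
VFSKNYASSTWCLDELVKILECKEKYGQIVIPVFYDVDPSEVRKQTGSFGKAFAKHEERF
KDDVEKMEEVQRWRIALTEAANLSG
>seed02
YDVLLSFRGEDQEKTFTSCLYDALKDRGIHTFIDAEELRRGDEISFALLKAIEFSRIAII
VFSKNYASSLWCLDETVKILECKEKYGQIVIPVFYDVDPSEVRKQTGSFGKAFAKHEERL
KDDVEKMEVVQRWRIALTTAAMLSG
>seed03
YDVFLSFRGEDTRKTFTSHLYEILKDRGIHTFIDDEELGRGDEISPAALKAIEESRIAII
VFSKNYASSTWCEDPLVEILECKEKYGQIVIPVFYDMDPSEVRKQDGSFGKAAAKFEERF
KDIVCSMEEVQRWRIALTEAANLFG
>seed04
YDMFLSFRGEDTRKTFTSHLYEALKDRGISTFIDDEESTRGMEISPALLKAIEESRIAII
PFSKNYASSTWCLDKLVKILECKEKYGQIVIPVFYDVDPSEVRKSTGSFKIAFAWHHERF
DDDVEKMTEVQRWRIALTEAANLSG
>seed05
YDVFLSFRGEDTRKTLTSHLYEAFKDRGIATFIDLENLRRADEISPALLKALEESRIAII
VAYKNYASSTGCLDEHVKILECKEKYGQIVIPVSYDVDPSEVRKQTGSFGKAFAKHEERF
KDDVEKMTEVQRWRSALTEAANLSG
>seed06
YDVFLSFRGSDTRKTFTSHLYVALKDRHIHTFEDDEELRRGDEISPALLKEIEESRIAII
VFAKNYASSTWCLDELVKILWCKEKYGQIVIMVFYDVMPSEVRKQWGSFGKQFAKHEERF
KDDVTKMEEVQRWRAALLEAANLSG
>seed07
YDVFLSFRGEDTRKTFTSQLYEALKDRGIHTFIDDQELRRGDEISPWLLKAIEYSRIKII
FFSKNYASSTWCLDELVKILECKEKYGQIVIPLFYDVDPSEVRKQFGNFGKAFAKHEGRF
KDRVEKYLEVQRWRIALTEAMNLSG
>seed08
YDYFVSFRGEDTRKWFTSHLYEALKDRGIHTFPDDELLRRGDQISPALLKAIEESRIIII
VFSKNYASSTWCLDNLVKTLQCKEKYGQIVIPVFYDVDPSEVRKQTGSFSKAFAKHEPRF
KDDVEKMEEVQRWRKALTEAANLSS
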