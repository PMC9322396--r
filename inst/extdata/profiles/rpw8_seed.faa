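>seed01
MGEAIVSEVLGRLGDMLIEEAVFLGGVRDQVEWLKRELRWMQSFLKDAEAKQAGNERVRN
WVSEIRDVAYDAEDVIDTYILKVASRRRGGFLGFLHKLSH
>seed02
TGEAIVSEVSGRLGDMLIEEAVFLGGVRDQVEWLARELFWMQSFLKDANAKQAGNERRRN
WVSEIRDVAYDAEDVIRTYILKDASPRRGGFLGMLHKLSH
>seed03
MGEAIVSEVLGRLGDHLIEEAVFLGGVRDQLEWLKRELRWMQSFLKDAEAKQCGNERVRN
WVSEHRDVAGDNEHVIDTYILYVASRRRGPFLGFLHKLSR
>seed04
MGEAIVWEVQGRLGDSLIEEAVFRGGVRDQVEWLKRELRWMQSFLKDAEAKQAGIERVRN
WGSEIRIVAYDAWDVIVTYILKTASRRRGGFLGFLHKLSH
>seed05
TGFAIVSEVLGRLGDMLIEEAVFLGGVRDQVIWLKGELRPMCSFLKDLEAKQAGNERVRN
WVSEIRDVRYDAEDVIDWYILIVASRRRGGFLGFLHKLSH
>seed06
QGEAIVSGVLGRLGDMLIEEKVFLGGVRDQVEWLKREDRWMQSFLKDAEAKQAGNERQRN
WVSESRDVAYDAEDVGDTYILKVARRRRGGFLGFLTKTSH
>seed07
NGEAIVSEVLGRLGDMLEEEAVTLGGVRDQVEWLKRELRWMQSFLKDATAKQAGNERVRN
WVSEQRDVAYDAKVVIDTAILKVASRHREGFLGFLHKLSH
>seed08
MGHCIISEVLGRLCDMLIEEAVFLGGVRKQVEWLIRELYWMQSFLKDACAKQAGNERVRN
WVSEIRDVAYDAEDVIDTYILKVASRRRGEFLGFLHTLSH
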