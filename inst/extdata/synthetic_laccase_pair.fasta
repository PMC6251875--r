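>synthetic_TvL_like synthetic stand-in sequence (not Q12718)
WRFGNNFHDAMPGAWKFLLMLTDCKWWSEMILDCHVSVLFHASAFAALMFCKQGWEASRG
RWINLGQDMAQCHMTMPVKIGCQTQFVPHMETWYQLACRMRKGVWSFSASPSSDIPDWQN
EWKCHVYIVEQPDPMDCTCEISTWQLHDGALRKQGKCNFRSTLLNNQGEGLCMPPVRRYQ
NRVTDLVILQHCWDDIIDYGCCKRCGHCSGIGNHTSDSWGPQIIWTLGWWYKHHRMAWQI
CYLCIGFKWQLLQKDPAISFHNQEVSNHTQAPTCHTPVFCWHGQDTGLTNQANGPWMSMM
PWADNFCYWQNLAIGLAHHARCFKVATNDYCMMTYSQSDCYTKTKYNETISGHPDNFMFC
RNYAVDYDAAYSNYQIMDFQNQFIPEWNRFGSHCGKHVYKIKMKWFNVMIHALMNSTIDW
KTGGTFIWQGTMNEEPALRKHDTTKAIVSCMYTWCCHLFQSYNQPEFEGRSWCTPRRDEC
ANVAWSCDIRLNIAAVRSYK
>synthetic_CuL_like synthetic stand-in sequence (not ALE66001.1)
QRFYLPFHDAMPKHAKFLLVDPDLKHWEEFILDDCVPVEWHASVFAALMFGKQGHEHSRD
REINRCQDMAQCHMKMCRQIGCKTTFVGHMETWYQCACVGVWSFTNSPAPDIPDWQNEWK
QHMYFVEEPDPMDCTRFISTWHLHYYALRKQGKCNFDSTLQNNQGGGPCMPPDYSYQNAV
PDLVILQQCWDGIIGYKCCKRCEHYSLIGLHTSDSWGPQIKWTLGWWIKWRRMAWQLCYV
LIGFCQQLLLGSKDPAQSFHNQEVSNHTTAPRCGTPAWCPHGQPTNLTNQANVPWMSMIP
TADNFCYWQNLAPGRAHHDRIFKVAENDYCMCTYSQSDCPTKIGFPECTSGHPDNFMFCR
SYASPYDANYFNDQIQVFQNQFIREQNPFGSHRDNHVYKINMKPFNVMITALMNRTIDWK
VKGTFIWEGTMNTEPALRKHDTTEVIVSCMYTWERYIDQLYNQPLMEQRSWFTYRRDECY
NMMWSWGIRLNIYEVNSYK
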