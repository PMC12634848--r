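>VSV-N nucleoprotein (synthetic)
EWQWSEPHWNMTFVIMFFDTEDKMSHWNTWTIFYCSLAFNYQFQKPKCSAYMPYLIDFGL
FDYRYKNAHCRACKVGGWDAMAEQKCVLVWMVTVNEEPTLGCCYASQHYYKEPPPFEKFV
PPQHYHDMHPLDCCEKPNTRFCSATEEYCNYDLENNVDAQDDCHECAMDSYDLHCHNNGG
GCGHNKDGMTMYDVCHMCSQFHFWGQLTALHGVMIRKHNMFVGIWTCVQDDTFWNEMIVR
KVAEEHEAWKTQWQIGLIHSVECICPQPGLIDEKQNARHMTFEKEDITETERYVFHKIEL
PIRIPLVRKPAQFPDNVSCCPNNKHALKMWHKNAWFMVYTEFYHLIVTTYMYETERTCEP
LSAVVTQVSPDQFNDDQGMHLVADRLPKHYQTHRCMKQIYMCIFGPYVLCHPYNSMHPYD
GT
>VSV-P phosphoprotein (synthetic)
HEHPIWAFWLGTSQETDMNMFVNSVAMCRAFRPTQCDMKPVIEFEDNDAITQDEDYEDRI
NVDPQRLNWVKSKLFLYLCGADHPVQCVYMQHMDNENDDMREYLKSYSRLFDVWPAVMTC
NPGNSTPHQVAEFHLLKNFRHDCFIHIWPFQPKKASLQPLMFGWHQLWQGTKSQLCMCIF
HCPHGMAWYEMIKRQQSNERAEKSNYELSGAYLFLTRLEDNLAIEDAALLRLPMFTPTCQ
MMRLDHELWCGETRYHLNSQMDSDC
>VSV-M matrix (synthetic)
VAQVYMHISMMAEAFWNFHWAAFKAFGVGTAMPIFRMIKMEICLYMMLLPPDEYDPKDYM
YKYKSVMQHICPGYFLSPNWWTDWYMTNSIIKTAVQQACFGPNYDTTRTPGRHFPDDNWM
PCRSECAWCRVDSGVECNRYCVRISKRNALECNWPNKRCNYLLISCGAQNKRRNEEHVKL
DPWKVLVRPYIKSLDANLAAAWPMSCVRECKRQYFLGCWPHHYLHFVYN
>LCMV-GP glycoprotein (synthetic)
VPPYTSFFTTVPVYFEMPAGEINRFSLVNPWVRYIYMGKEGQLPHSRAYEEYDPIRQGIE
TTATTRINMINCVWMWMMVGYRNIYDWMGCVGDVWCPTQEAVNTMYTDNNRWWPLFFQCT
KQKVMWGIITMMLRTCHVLNMHDLYQPPQAKWPPFSSNIRYFMRYSLGKMNYIMLGDHVT
LEQWKIWQNDCIGFEWNDHHPSCQMWMGNNCRSMYNMTQYDAWMGWAWDDWKWHKFVELH
RYWVLMFDWWCPRHGRALHKHMHVFGCCKTHKHSTGAERVNPSGNWCITNAVEEKYDPIM
HAIHDADRMEDESEEKTSWAKFKTNIENWGFESQKRDDCQPHPGRWFGYKIVWSDLKSYQ
GRSEICNQGNNVTYMNCFCTWAIRLGWRCCTLAKYGWMYKQPICRHYDSMARDHWCFCGV
GMKHMDTCALYIHKGKHSIRIVVDWVPNHSNANSMFWLCEMTLGNACNCNPCWLRVCITS
ETEANNKEWWEGLQIWPW
>VSV-L polymerase (synthetic)
APAFPYDVPAIRRALFTSWEDKIFFGEPTFGRCAVPPNCQRMPIKCCHKYLWTVIKMAWN
MPWHRDVSVQREVEDYVWELTWVVMIIFYSYKRLQRVHDKHCPVMHCWWQMKIWNRNWAF
DEPWFFEDQLIEPDNAPVWTSFTWHRMVDWDVMWHWYWVIQASAGWAAAKSCNLEWHVSG
ARLNNFNLPFSLNIDCTWMSMHSMYTQLGTDAFHIYMSWDPAHFQQTHTYFLCGQLDGLI
TGMQFMFNNRKPGQTVIESYSPEMMSEWIQIFYTANTTHGQGQEKDMTMDENSHQACPNW
HRSHPTVTKTCWDLYVLNYFNKKEGLHGNWGLYIAYFICMGVIEPVMPKDMNAIGMKLDM
TQCFAAEPFFEMVEGYGEVFWENYAHNSSIQKYFGKINKITPQAGWLIEVGCIWPLDHWH
NSPFRPIYNCFSSNRCDDRMKNFGATLFIHSAIKTVASEYVKDQLPKYPTGHEIARIRDH
RYWCNWEPDTDRRKMKMIISLNWMMAASPRELAFPAVYDIHYVWMTTHTCWDFKFTESDW
HILKTLRGVDINQCFPTFQSTADPHYNWRRKDASTLWWVVSQIVTDVHHCWWWHDVACWY
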