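>P03995.4 synthetic stand-in (mouse GFAP alpha, real length 430 aa)
KPIKITAGQYRWHVMKSKAPTDYPLMEVHCHDKRCDVRFKIYETTLPQNSKPNWFPFPWM
CDSWHMGKIIYRTKRHHHRFDWNTSHIHLLFMPPMSHPKTRGGGCKMPACRWSRHSCDLG
NAYQIFWEFSSLADFTRCRYLSCMWICKQITEGAFHLKLSELFLMEIGSSSLNTLEVAHN
VIIRCSDGTVQTMDGEHFNKILIYQADMLMMTFVLKRYWAQNTAFCWTIMVPKPAEDTCI
ENFALQSPNGQPMSKQWVEYPMAVASYIQFTDGRYPYDDCLVPAGSMPWTEICQHHYKLL
MHVTDVPERIPSFSGRRDLREARENDGDFFSNMLFGWFRLDKWWERLNSCGYYRQMVQIH
KNGSYNEPCIEFCTLCGSTVECFMNKMYDDAHKNSRASLWPACFMIYVCSDRNYTMEVQN
CYYENCRGLY
>NP_001124492.1 synthetic stand-in (mouse GFAP delta_epsilon, real length 428 aa)
WECHRYQIHMLSVFLDNRGPIDEQGLQIMETDQAKCYKTVSPCYPAKHNPMSSNQDDEDW
FLMYKVHHNSCLHYYIGNALMTWTCYRHIIRSLSTGSDAMVQVWKLQQLYDVAHDKNFSH
ENDHQGCQGTKMNYCEKDKVICERMTSMWKWNPDAMGAIYKISCHICCFWDFKGCAYDEI
AYCRTGTIHMRHANVYMRVSDYNQWFEKWAAVHIARTLVVTPIDHCYFCMDYLQFDPWYI
YWCWWSSVDSSWCAITVEKWFPQVPSPKHSICPCCECEAYFWKKFIEVEIGWNHHEIMML
WDRWPGIIKTKHVFTSAPANKWMWRGYKKDNWQFMSFPCSGTQTICIEQRAYVTQPLQLI
SSQYCEPFQPYKHGHGILHCERQGPGQMQIMMMLPDGDQSTGPTWVVKMIVENRNFQFFA
NHYIVDSD
>synthetic_mouse_kappa synthetic stand-in (mouse GFAP kappa, real length 435 aa)
WYQPVLQSDHHHHDRAFDRYCMDVVTYADSESVKGKFERITITIQIHVKQLNWDFGGETV
RNNSDPKSPFQNINYLIRFTIDIIDMTQQDYFFKIEYGAYITRARRKYPDSDNEVYDEYC
CGMLRIWHNYDVIHFNFLFFKGWGEDHSHSTNAYQWDMKLFVVYPYHKWFNPKNKYRHMP
TKVHAYCNQAWMVFHRMHMTCHQHGDVKDLMMAYKASWFYSQHDWGDDNTMNKEAMRTLG
RCLTIRGIPMVSPLTALARVHCNEGKIRGETNIAFPCAHPSWHACTGLNNWQIGYIEDNT
AARGKNHGVHETMCVGTYMKFFDYFMHQYQTPGGDLAMYDPHLHYMALNAAIGNMVLPQL
FCQRFKYLPEESVQQQRCFMYTGQNHGAFDWDMQQYWVLYCTCLITSSWMDIDLHEGHLM
RMKQVKKAAHMKTFH
>NP_002046.1 synthetic stand-in (human GFAP alpha, real length 432 aa)
NFYQIFQHKGQWADKFGNIQQFMYWMSSCPECAKEVFEQGMMMPPWRWSDSCGVGEGCVP
WVQRPQQRNDHWMGHVLPLYNDDNDQACCHPSIIWPYYPWNPMDREWQAECEWDRPAIKW
EAMPHPCAGIFHEVACNFWWWDMSTTVPKTHHCITQMNMQSMAVVHNGFIGKNSWYCFPH
NRFIHSGNQTQKDVRGRPEKWKDGYFRERESAYIVGNWMQNFSLSPSFDCATEKHNEIWC
SFPFEYDVSSIWANIHTAMNMFPADFSSWMMYAVPVQQFRMPVTKHFMCRWQCGHVPHCD
HAQKIVTMNPQVANAVQTNHFTFTKCMMQYWMGWMEEPASTNEWKTEGRSFSNLHMRHYK
QYHDCYEELYCPWIQACEPVFYIFCFCESQSPFAAFTDDWSYNKAIFGLSMYNRMEPKCR
WMGSTVHSDQIL
>NP_001124491.1 synthetic stand-in (human GFAP delta_epsilon, real length 431 aa)
GQANMELHEAPQHPMHQVERLCSIIMYNFTMDFESWRWMNTHKTQHYHAPNWCCNLCIRD
DVRHSTAPWGQGLAKITWMFLAAHMAYVSTTNTLAVSHFGNHRWIAWVEDDTHPPNPESY
KRPKMDCRSDCNALFTFMTRAKENAVHMYPWHMSVKEMTGSRSIEKAFNEMKAHQPYNIV
HKMDAQKDVNAWRKKAKIPLFESNDIDREKPEGKEIINDKWITFKYPSQRATSLEYIYIF
GRTESVKTGSTGFKTMTLFGYQFCDMLPLDMDKGKMAWSTEHNVPLIADINGEYHIHVRH
PRDCNHQMIIARWMAVFSNLSGWVWKHHYLLACYIAINLQRRTHHHDLRWAAWWMEKLRL
ECNVVDGIHNRTWNDESRQWEVKSPGKRFSQICGIVIHYGRKWRKWCGKICGFANWEFWG
PIWAWRKFYQA
>ABL14186.1 synthetic stand-in (human GFAP kappa, real length 438 aa)
CKQWEGQNCKGLKAKFKSCGMDKGSNTEKAGHCQHRYENPKDSGTYTVVEYVHFYEVGVK
EVTYYPTRLEWYFFALYGDQTSPHTKDNYWLRAEMVWYVWKYRHFQNDSWMYLEVFCFEL
GQNEDWSELEFYPNIRITHYTFYEQLFFCYTSHANLICQKFVEAMWADKRQYAHKWVIHQ
DCCTQWDKREVPDPNSFVMDHWLSWCPINWHVEEQFTFSRAWLDGAWTDKSCEFVHSDRG
IYPLPKIDTMQNTCKRFGIEKPYMAMFKVAYHQTAHNEHTAEICLEHSVWCNQAKKWSYC
KLTNLQLQEYGFNNIMDQVWYWGYIFWHSTQREKDHYNTWSYSDISGFRAIKDELEYKLF
RYWWYMYWCPKYMWAQDNNYYWYQFPLLFAMIDYYINCRMPRPRCMKLCWIFMVVCVCWP
MMHEWMSHCINHSRPREY
>AAD01873.1 synthetic stand-in (rat GFAP alpha, real length 430 aa)
GQMFTCERTDHRNLSQSCGIYYPINQDIQTLESQTTRQRCSMNFLVKANCESSTSTDRLV
DVMMGTRFSDSTVWEDCEPKGKYVMTSNFKPKIASHCCIQCPSILQIPFHLADELAGTEW
KRMCQVRNWQTWLPREVHIMQRTKWTMYTCQWVDVKQMMQRCYYACTHTMKAWKQCIKLY
MDQTSHIPLSGLLVNEVTSVGASEMWITHEHYPSKPKFKYTNLYSTNMLIVWKNAKCDIE
NDRKPLTFARWHWHYAFNCRPYKSCKHDWRSLHGPQWHFHKCASCPRFWSLDNNYKWFMT
MDCVCWEKAAQMKSRISKGHRARRWVYARYEDGTWWFIHCKCMPCPDYYMCFPVPKTPVK
AIQDVAPIVYHYHRRFTCTRGLGTIHGQWYRLQGICRYYLKCHWKVLWYPRLLQQAFDTK
KVFKYYNNCG
>AAD01874.2 synthetic stand-in (rat GFAP delta_epsilon, real length 421 aa)
QMTVIMFNALLVHHYHGLGVHSANIAPNIDCVCNSRHDNWFGRDKLTFYGGTNMKMPIHA
AQWVYKVVMLCVQEGWLTPSHPESHIDIMRMSTACYIYHVEIRPYCCAQHTLRHMLDNVI
KVYMCRSPFVIQLAIVARNQHNNYGWMIGRSIWTFIPFGGNHTFYLFYPQRGADPPLDDG
ITDRNPHIYRKAVYPDFFHHNVRDSSEHGSNSSYAFYQKRMECDSTKTEFHCAQPMWLKC
DDCHAFCKTYNKTMWIFMGFVFHWCPTKGNRDVPTRWDGAEPHGYAGKYNKTILHHAIMC
VMRIVNLYNGKVFIREADIYWWWPAVQKKSSGAIYWRKCQVCNCCGHEPGPAKLLEVICS
DRTVSCKEDTITSFPRGVNGHKFRRPADWNGKAYAAFTPALEGSRVKKYSMNVDQNARFP
C
>ABL14185.1 synthetic stand-in (rat GFAP kappa, real length 409 aa)
NGTYFVVHNEDMQGHGNTKLCQCSCSSQPHLYSEFCLHKFAKSTNSALCCIGREPDGYQA
FKVTGFLLHQFNWLCPINQGLDWNAYMDPPHHQFQKTCQYCNSIYVIRMCMWCRWLQGVS
LGPDEKGEWDKTLAGIAILADSQLYLRVPRQQRDSMINIMHFMLPRWGMRIAELQLHLWF
NLDKENNWCMCANADGEILSCLKYMWFSDQAQNNYKPQPGSNAHMFGQDDFYGWADLDQM
ITEWTWTYIDQRCWEGYAISMVCDLHTFIINEDVPLLYRLDVQQPVNISSPIVMLTPKPG
EFYHTMYRMMERNEKLWNNGAWMAYTVMWPRDYNMYDDVGDKTAWDMKNYQAQIAMMYIQ
NSWVHMAQGNHHHQPNKVSPAPTYPCPCWRYYVTSYDYCWKMVNDKSFS
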