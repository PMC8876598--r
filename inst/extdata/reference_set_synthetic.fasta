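>TOXFAM_A category=toxin synthetic exemplar; family A scaffold C1-C2-C3C4-C5-C6-C7-C8-C9-C10
LTYCWTLQQTETCHTCCIHSMFGCQGCFQIKLCAYWCQDEMGKQCSMCYPGIMQ
>TOXFAM_B category=toxin synthetic exemplar; family B scaffold C1-C2-C3C4-C5-C6C7-C8-C9-C10
HNLGDCLKIMYTHQCIMAGQPVHCCYLSHEHACTACCEEPKDVCMVHGMCWWSFLLICAFWGKV
>TOXFAM_C category=toxin synthetic exemplar; family C scaffold C1-C2-C3C4-C5-C6
KHCFGCINYDAMQCCMINFDGCVHLFDYMSCEKM
>TOXFAM_D category=toxin synthetic exemplar; family D scaffold C1-C2-C3-C4-C5-C6-C7-C8-C9-C10
WNCTEHCKSQCITVCNNMACIIMYCIYPCAAQLKVNCNAPQWTACVSMSQWVCNSKYII
>TOXFAM_E category=toxin synthetic exemplar; family E scaffold C1-C2-C3C4-C5-C6-C7-C8
MGGSNACVMKCQMCCVFQTFCDNEFCHKCQSYDCQTYEIF
>TOXFAM_F category=toxin synthetic exemplar; family F scaffold C1-C2-C3-C4-C5-C6C7-C8
QEFCHVEMDCMPGKCWIWKFIMCLNPQEPFFCPKCCGVIAYCKVKKSQ
>TOXFAM_G category=toxin synthetic exemplar; family G scaffold C1-C2-C3-C4-C5-C6C7-C8
GKKCYGPVLACVQGICGKEKCTSGCTQEDQQACCFDNCDWTDV
>TOXFAM_H category=toxin synthetic exemplar; family H scaffold C1-C2-C3-C4
AVCPACHDFCSACPQMFDTVTNNL
>TOXFAM_I category=toxin synthetic exemplar; family I scaffold C1-C2
STSHCEGVHLCTWPWQHVNNPWPE
>TOXFAM_J category=toxin synthetic exemplar; family J scaffold C1-C2-C3C4-C5-C6-C7-C8
PNDCVTCFHNHKECCDVWGDVCYEVSDKCEINMMLVCKNVHGCTVS
>TOXFAM_K category=toxin synthetic exemplar; family K scaffold C1-C2-C3C4-C5-C6
HTANTGCGYWANCQNCCWMCAMDLQLCWSELDL
>TOXFAM_L category=toxin synthetic exemplar; family L scaffold C1-C2-C3C4-C5-C6
QVPCYDWMQMCKHMCCEYAQGMYCDDVDQPCPVSI
>TOXFAM_M category=toxin synthetic exemplar; family M scaffold C1-C2-C3C4-C5-C6
WQQEDCKHYEFYMCKAESKMPECCFIVMMLVQCGHKQNGCHHYNYP
>uSpTx-Hp1 category=toxin mature peptide of mu-Sparatoxin-Hp1 (Edman/MS-determined)
ADSGGDAGGDAGADDEGSCKWMFQSCEPPAKCCDGWTCYKGRCNLIL
>uSpTx-Hp2 category=toxin mature peptide of mu-Sparatoxin-Hp2 (Edman/MS-determined)
DDDKKECIGHMGWCAWTDGECCEGYRCKLWCRKIIDWL
>HK_RPL7A category=cellular synthetic housekeeping exemplar (RPL7A-like)
MLEKAPDPTGGDELEGKTLKAVPTSTVSGGIPGFKKDQPGAGTKGPHIRSNLKLVALLFGTAPDQAIGNNARVMPAQRVNDPFDVIEGLGVLDYVFKAQYWAYEGRWEKLRITMNGCTDTLGVKGYASGAKEHDKLLIL
>HK_RPS4 category=cellular synthetic housekeeping exemplar (RPS4-like)
MARRLGNITFGVSVFELALIYTIRWRTDNLNQEFSDNIPSQEVSGRGDTGDKIFWNIVLLGPTAVCEGPPVQAKKVPEEGKRVTDMEEGVECERQETTSCYQKHYTQDLASGVMDRDQSDFLPAPSISSYRRGEYERPGSGRKREHNLI
>HK_RPL13 category=cellular synthetic housekeeping exemplar (RPL13-like)
MWIVVQSDESETKQFDSTETPTLGATFFTNAMADTQSPAQITRAFNDQYDAQERMEVVTGKKEEAISGVVGEDSVSMRDSRSLELSICNGPICLNRGKLPPSRVKAGEVDVSGLNLWSVDYEMTSINLE
>HK_EF1A category=cellular synthetic housekeeping exemplar (EF1A-like)
MLMQVLLHSIRYCILAWISLMRDREILFFVDYKEWMHMTIGESLWIQNSNSTGCPYKNLLSGVATNLRNSKGTLIVESEEGNLLDCSQKTWGPEGLGFGVGDRTGFDQFYLEKRNPRKAGLPKEDSRSSALVVSDITNVFPWMTFAKTPVSFYAMECPDYLLAVQ
>HK_ATPB category=cellular synthetic housekeeping exemplar (ATPB-like)
MITLVAADTMERATLQEPIAGSKVGVAKHVSTNELIDGIGAVPRINLMLRWLIATTASWNGAFGEIVELYNYQLTSFPPTLPVKHAEFSNDDTFKNGFPILCKFDAESLRYQGVGAPVSPFAYGEHDSHLLQGCFESLEGESTSRQNYKQHITGTEADVT
>HK_TUBA category=cellular synthetic housekeeping exemplar (TUBA-like)
MYVIFPGQSDVGREAARDWGKSNYGRLKGREVILCTQNVTHLPTSQEVDHLIRHVKIQQDLHLDFHKDNLMELGGLCLLAASQCEKKPYNAAIVAFVISEPIKTERGEANPERLNFLADLQVVPFSDNAISRSLKCLTHHIPGNHRNFMDHANNMLGIHVQGAVTGGRASLSSVKIREYQF
>HK_ACTB category=cellular synthetic housekeeping exemplar (ACTB-like)
MTFDSADWGQVVDRKRSTEQWSKGNGIEVMGSQLRVGRVGANTEYVFGATVRVMMVMVPDNTNGIYPIYYRGKDLMFRSTTEKVADWSNGQNKDRSKTLPKDEDCFFEHNSCSTLPRMTELGENACKA
>HK_HSP70 category=cellular synthetic housekeeping exemplar (HSP70-like)
MQEPTLPKLEQSLQSVALDGARIHSPRPLSSVRSIFAWEYASDLTTQFSEPLLELEAGMACINGKCMAVGWIKGLEGVKLAGQDNVNYYGMIIIPSTTCVANSWCRSCLPKAMHAPSHAAVMLSPIAYTTVGGVKTLERLSSYLPKTSIGSRIEFLATNTSKSPLIDHGRMA
>HK_GAPDH category=cellular synthetic housekeeping exemplar (GAPDH-like)
MQVLVKEISAPCRHNYVEAGYLIILPSGERMDVRQARTRYAYVADLEGQEITAFQNPVDMFQFASHVDHKFKAEVFEQRDLLTTKVFANMVRELENGGRPAVPDKEHTQHAVDPYLSVAGSEVKIAFGARHELLLLIIINPASRKQLPIVTE
>HK_UBQ category=cellular synthetic housekeeping exemplar (UBQ-like)
MTPITHTSSSLIGLVDQPESYQDIKGKEVALASVQAIKESELTVSDYQQVVIVPIGLEYNDNMTIRPPKIAPNTYVVIAFRDSFAAKPGMGSFPQKNPLYGITDLGQAARAGSYRHYWPKLHAPFTDSRPNPLTLMAGPRAKVSKRGH
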