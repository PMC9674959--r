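>OCTN2_synthetic_L557 synthetic stand-in sequence, 557 aa, 25-region transporter topology
TTEPSPWKKYDDNKTTGDNNWRHWDDRAYHEWPLESYQHETHHDLSIETYMWLLPFAVAS
KYCVTCWHPTTGSNNQRYYKHETREWTVNLWVCVRHHPKEMSKRPQHGSERHRSQHARTK
GLDRETPEERARDCSYICLATIVCGISICLVQIMICIQGMRLPPEEQTFIFHGTSCFILD
VCMYVACMKQWEYALITCWLVVSMPEVFFPDCVSKQQRRETEHSHQIAMFGYACIWMVLV
ISSHMHHHDNEKEKKVVSMLGTIFHRHKCYVVSTITEPKDWISHTGGHYRWAYATHWSAS
TPSQSRGFWSPHYKDTEKPRRRRRPRYFRKWYNWDYHQMNVHCLYVFAIILWVGMILGEE
YDRDNQSDNFTIASFFIACVYMFPMVYHLLGEFNNNDDDAQWCNMLMTLLWPGMCSHDVT
CCCGKEMDLITNFLTSICCDVFNLWKEEKRRHDQNPDQLPSSSVHGHSYIMCMSEIIRIM
GPNAYHHDTDQPCVMECTFVFNWFGLWFAFTLLWGEHFKYRQQPTWPYEQRHRCKHGGYR
HEGDKTDEQHKYMMDSD
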