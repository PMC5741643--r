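>syn_YS1
MKLFALVLALALVSAAEAGS---KDS-------------ETVKAETLPSEKVAQNTLSLAEKTLAENYSLQKALTKGLPACGQT----CVGGT--CNSPG----CN-CTWPV--CAR---NSLAT------
>syn_YS2
MKLFALVLALALVSAAEAGS---RET-------------ETVKAETLPSEKVAQNTLSLAEKTLAENYSLQKALTKGLPICGQT----CLGGA--CNSPG----CS-CTWPI--CSR---NSLAA------
>syn_YS3
MKLFALVLALALVSAAEAGS---KNA-------------ETVKA--LPSEKVAQNTLSLAEKTLAENYSLQKALTKGLPTCGQT----CVGGA--CNTPG----CN-CTWPV--CTR---NSLAA------
>syn_YS4
MKLFALVLALALVSAAEAGS---RQS-------------ETVKA--LPSEKVAQNTLSLAEKTLAENYSLQKALTKGLPACGET----CLGGS--CNTPG----CT-CSWPV--CAR---NSLSA------
>syn_YY1
MKLFALVLALALVSAAEAGS---KDT-------------ETVKAETLPSEKVAQNTLSLAEKTLAENYYLQKALTKGLPTCGET----CVGGA--CNTPG----CN-CTWPI--CTRS-------------
>syn_YY2
MKLFALVLALALVSAAEAGS---RES-------------ETVKAETLPSEKVAQNTLSLAEKTLAENYYLQKALTKGLPICGDT----CLGGA--CNSPG----CN-CTWPI--CSRS-------------
>syn_YA1
MKLFALVLALALVSAAEAGS---KES-------------ETVKAETLPSEKVAQNTLSLAEKTLAENYALQKALTKGLPACGET----CLGGS--CNTPG----CN-CTWPI--CSR---NSLSA------
>syn_YA2
MKLFALVLALALVSAAEAGS---RNT-------------ETVKA--LPSEKVAQNTLSLAEKTLAENYALQKALTKGLPICGQT----CLGGT--CNSPG----CS-CSWPI--CTR---NSLAT------
>syn_HF1
MKLFALVLALALVSAAEAGS---KQS-------------ETVKAETLPSEKVAQNTLSLAEKTLAENHFLQKALTKGLPTCGQT----CLGGT--CNTPG----CS-CTWPV--CAR---NSLSA------
>syn_HF2
MKLFALVLALALVSAAEAGS---RDT-------------ETVKA--LPSEKVAQNTLSLAEKTLAENHFLQKALTKGLPTCGET----CLGGT--CNSPG----CT-CTWPV--CSR---NSLAT------
>syn_FA1
MKLFALVLALALVSAAEAGS---KDA-------------ETVKAETLPSEKVAQNTLSLAEKTLAENFALQKALTKGLPACGQT----CLGGA--CNTPG----CT-CTWPV--CSR---NSLAT------
>syn_FA2
MKLFALVLALALVSAAEAGS---RET-------------ETVKA--LPSEKVAQNTLSLAEKTLAENFALQKALTKGLPICGET----CVGGA--CNSPG----CT-CTWPI--CSR---NSLSG------
>syn_FA3
MKLFALVLALALVSAAEAGS---KNS-------------ETVKA--LPSEKVAQNTLSLAEKTLAENFALQKALTKGLPICGQT----CLGGS--CNSPG----CT-CTWPI--CAR---NSLAG------
>syn_FA4
MKLFALVLALALVSAAEAGS---RQT-------------ETVKAETLPSEKVAQNTLSLAEKTLAENFALQKALTKGLPACGET----CVGGS--CNSPG----CT-CSWPI--CTR---NSLAA------
>syn_HS1
MKLFALVLALALVSAAEAGSTVPRDEIATNTKLQETVAGETVKAETLPSEKVAQNTLSLAEKTLAENHSLQKALTKGIPTCGDS----CIWLP--CVSSGIG--CS-CKTK---CFR---NSLAT------
>syn_HS2
MKLFALVLALALVSAAEAGSTLPQDEVAA-TKLQEAVAGETVKAETLPSEKVAQNTLSLAEKTLAENHSLQKALTKGVPTCGES----CIWIP--CVSSGIG--CT-CKSK---CFR---NSLAG------
>syn_HS3
MKLFALVLALALVSAAEAGSTMPEDEFANNT-LQENVAGETVKAETLPSEKVAQNTLSLAEKTLAENHSLQKALTKGVPVCGES----CVWIP--CISSAIG--CT-CKTK---CYR---NSLSA------
>syn_HS4
MKLFALVLALALVSAAEAGSTFPNDEMAGNTKL-EQVAGETVKAETLPSEKVAQNTLSLAEKTLAENHSLQKALTKGVPVCGES----CVWLP--CVSSAIG--CS-CKSK---CYR---NSLST------
>syn_HS5
MKLFALVLALALVSAAEAGSTIPRDEVANN-KLQ-QVAGETVKAETLPSEKVAQNTLSLAEKTLAENHSLQKALTKGVPVCGES----CIWIP--CVSSGLG--CS-CKTK---CYR---NSLAG------
>syn_HS6
MKLFALVLALALVSAAEAGSTVPQDEFAGNTK-QES-AGETVKAETLPSEKVAQNTLSLAEKTLAENHSLQKALTKGIPTCGDS----CIWLP--CISSGIG--CT-CKTK---CYR---NSLSG------
>syn_NS1
MKLFALVLALALVSAAEAGSTLPEDEMASNTKLQETVAGETVKAETLPSEKVAQNTLSLAEKTLAENNSLQKALTKGVPTCGES----CIWLP--CVSSAIG--CT-CKTK---CFR---NSLAT------
>syn_NS2
MKLFALVLALALVSAAEAGSTMPNDELAT-TKLQEAVAGETVKAETLPSEKVAQNTLSLAEKTLAENNSLQKALTKGVPVCGES----CVWIP--CISSALG--CT-CKTK---CYR---NSLSA------
>syn_NS3
MKLFALVLALALVSAAEAGSTFPKDEIAANT-LQENVAGETVKAETLPSEKVAQNTLSLAEKTLAENNSLQKALTKGIPVCGES----CVWLP--CISSGLG--CS-CKSK---CFR---NSLST------
>syn_NS4
MKLFALVLALALVSAAEAGSTIPQDEMATNTKL-ENVAGETVKAETLPSEKVAQNTLSLAEKTLAENNSLQKALTKGIPACGES----CIWIP--CVSSAIG--CS-CKSK---CYR---NSLAT------
>syn_NS5
MKLFALVLALALVSAAEAGSTVPEDELAAN-KLQ-QVAGETVKAETLPSEKVAQNTLSLAEKTLAENNSLQKALTKGVPVCGES----CVWLP--CVSSGLG--CT-CKSK---CFR---NSLST------
>syn_NL1
MKLFALVLALALVSAAEAGSTLPNDEIANNTKLQESVAGETVKAETLPSEKVAQNTLSLAEKTLAENNLLQKALTKGIPVCGDS----CIWLP--CVSSALG--CT-CKSK---CYR---NSLAA------
>syn_NL2
MKLFALVLALALVSAAEAGSTMPKDEVAG-TKLQETVAGETVKAETLPSEKVAQNTLSLAEKTLAENNLLQKALTKGIPACGDS----CIWLP--CVSSGIG--CS-CKSK---CFR---NSLST------
>syn_NL3
MKLFALVLALALVSAAEAGSTFPRDEFASNT-LQEAVAGETVKAETLPSEKVAQNTLSLAEKTLAENNLLQKALTKGVPVCGES----CIWIP--CISSGLG--CT-CKSK---CFR---NSLAT------
>syn_GA1
MKLFALVLALALVSAAEAGSTIPEDEIAGNTKLQEAVAGETVKAETLPSEKVAQNTLSLAEKTLAENGALQKALTKGVPACGES----CIWLP--CVSSGLG--CT-CKSK---CFR---NSLST------
>syn_GA2
MKLFALVLALALVSAAEAGSTVPNDEVAS-TKLQENVAGETVKAETLPSEKVAQNTLSLAEKTLAENGALQKALTKGIPVCGDS----CIWLP--CVSSGLG--CS-CKSK---CFR---NSLAG------
>syn_GA3
MKLFALVLALALVSAAEAGSTLPKDEFATNT-LQEQVAGETVKAETLPSEKVAQNTLSLAEKTLAENGALQKALTKGIPACGDS----CVWIP--CISSGLG--CT-CKSK---CFR---NSLSG------
>syn_GP1
MKLFALVLALALVSAAEAGSTMPRDEMAANTKLQESVAGETVKAETLPSEKVAQNTLSLAEKTLAENGPLQKALTKGVPACGDS----CIWLP--CISSGLG--CS-CKTK---CYR---NSLAT------
>syn_GP2
MKLFALVLALALVSAAEAGSTFPQDELAN-TKLQETVAGETVKAETLPSEKVAQNTLSLAEKTLAENGPLQKALTKGVPTCGES----CVWLP--CISSAIG--CS-CKSK---CYR---NSLSA------
>syn_RS1
MKLFALVLALALVSAAEAGSTIPNDEFAANTKLQETVAGETVKAETLPSEKVAQNTLSLAEKTLAENRSLQKALTKGVPACGES----CIWLP--CISSGIG--CS-CKTK---CYR---NSLAG------
>syn_RS2
MKLFALVLALALVSAAEAGSTVPKDEMAN-TKLQEAVAGETVKAETLPSEKVAQNTLSLAEKTLAENRSLQKALTKGVPACGDS----CVWLP--CVSSAIG--CT-CKSK---CFR---NSLAA------
>syn_RS3
MKLFALVLALALVSAAEAGSTLPRDELAGNT-LQENVAGETVKAETLPSEKVAQNTLSLAEKTLAENRSLQKALTKGIPTCGES----CIWIP--CISSGIG--CS-CKSK---CFR---NSLSG------
>syn_RS4
MKLFALVLALALVSAAEAGSTMPQDEIASNTKL-EQVAGETVKAETLPSEKVAQNTLSLAEKTLAENRSLQKALTKGIPACGES----CIWLP--CVSSGLG--CT-CKSK---CYR---NSLSA------
>syn_RS5
MKLFALVLALALVSAAEAGSTFPEDEVATN-KLQ-SVAGETVKAETLPSEKVAQNTLSLAEKTLAENRSLQKALTKGVPVCGES----CVWLP--CISSAIG--CS-CKSK---CFR---NSLAT------
>syn_RS6
MKLFALVLALALVSAAEAGSTIPRDEMAGNTK-QET-AGETVKAETLPSEKVAQNTLSLAEKTLAENRSLQKALTKGVPTCGES----CIWIP--CVSSGLG--CS-CKSK---CYR---NSLSA------
>syn_PN1
MKLFALVLALALVSAAEAGSAESLVK-PN--------DSETVKAETLPSEKVAQNTLSLAEKTLAENPNLQKALTKGIPACGES----CVWIP--CISSGIG--CS-CKSK---CSKG-------------
>syn_PN2
MKLFALVLALALVSAAEAGSTQAIEN-AN--------DTETVKAETLPSEKVAQNTLSLAEKTLAENPNLQKALTKGIPVCGES----CIWIP--CVSSAIG--CT-CKTK---CTKG-------------
>syn_PN3
MKLFALVLALALVSAAEAGSSKDVLT-LN--------ESETVKAETLPSEKVAQNTLSLAEKTLAENPNLQKALTKGIPVCGES----CVWIP--CISSAIG--CS-CKSK---CTKS-------------
>syn_PN4
MKLFALVLALALVSAAEAGSENSAKL-PA--------ETETVKAETLPSEKVAQNTLSLAEKTLAENPNLQKALTKGVPTCGES----CIWLP--CVSSALG--CS-CKTK---CSKG-------------
>syn_QD1
MKLFALVLALALVSAAEAGSELTNKA-PN--------DSETVKAETLPSEKVAQNTLSLAEKTLAENQDLQKALTKGIPTCGDS----CVWIP--CISSGLG--CS-CKTK---CSKS-------------
>syn_QD2
MKLFALVLALALVSAAEAGSQANEIT-AA--------ETETVKAETLPSEKVAQNTLSLAEKTLAENQDLQKALTKGVPACGES----CIWIP--CVSSGIG--CT-CKTK---CTKG-------------
>syn_QD3
MKLFALVLALALVSAAEAGSDLSKTV-LN--------DAETVKAETLPSEKVAQNTLSLAEKTLAENQDLQKALTKGVPTCGDS----CIWLP--CVSSAIG--CS-CKTK---CTKG-------------
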