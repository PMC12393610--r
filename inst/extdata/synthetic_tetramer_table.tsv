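tetramer	value
AAAA	5.412020446034148
AAAC	5.2635932308621705
AAAG	2.7526558935642242
AAAT	6.220636948943138
AACA	5.812422264367342
AACC	7.5691419292707
AACG	5.864502581069246
AACT	4.441978725837544
AAGA	7.528990632388741
AAGC	1.6608769472222775
AAGG	1.1731885974295437
AAGT	1.7711481479927897
AATA	1.265191508922726
AATC	4.356867926660925
AATG	2.5632163293194026
AATT	2.9026694430503994
ACAA	7.642374865245074
ACAC	2.6797051534522325
ACAG	1.8483247836120427
ACAT	1.687518460676074
ACCA	1.048961317865178
ACCC	2.638688056729734
ACCG	6.631791535299271
ACCT	3.034422474214807
ACGA	7.087569991359487
ACGC	7.120166105451062
ACGG	3.646228954894468
ACGT	5.637795205693692
ACTA	4.235411217669025
ACTC	2.1489499495364726
ACTG	1.696929250843823
ACTT	1.7711481479927897
AGAA	7.47424594219774
AGAC	7.99118856433779
AGAG	1.6549285186920315
AGAT	4.890015732496977
AGCA	5.313126390334219
AGCC	6.442757433047518
AGCG	6.564540888881311
AGCT	1.723510425304994
AGGA	3.6084637325257063
AGGC	1.2983933696523309
AGGG	1.973130733706057
AGGT	3.034422474214807
AGTA	7.332704310305417
AGTC	3.1505364344920963
AGTG	4.832075883867219
AGTT	4.441978725837544
ATAA	2.92370141367428
ATAC	7.679225921398029
ATAG	6.065726656001061
ATAT	5.110140935750678
ATCA	3.627398237818852
ATCC	4.917425858322531
ATCG	6.755816716235131
ATCT	4.890015732496977
ATGA	6.677516915136948
ATGC	2.469312011031434
ATGG	3.7654772016685456
ATGT	1.687518460676074
ATTA	3.88102945452556
ATTC	4.966972351307049
ATTG	4.300069647375494
ATTT	6.220636948943138
CAAA	5.252013512887061
CAAC	5.332334670238197
CAAG	3.77099291770719
CAAT	4.300069647375494
CACA	6.482738885330036
CACC	4.508875816594809
CACG	3.107120940228924
CACT	4.832075883867219
CAGA	2.520211693365127
CAGC	1.6437752253841609
CAGG	6.337369472719729
CAGT	1.696929250843823
CATA	4.424036076758057
CATC	6.551711631240323
CATG	3.427416314603761
CATT	2.5632163293194026
CCAA	3.1373709852341563
CCAC	6.185481884283945
CCAG	5.831009793560952
CCAT	3.7654772016685456
CCCA	2.0062128943391144
CCCC	3.295001340797171
CCCG	4.474623198155314
CCCT	1.973130733706057
CCGA	2.7161956147756428
CCGC	6.41512509342283
CCGG	6.744108986109495
CCGT	3.646228954894468
CCTA	3.695137210888788
CCTC	1.1844816978555173
CCTG	6.337369472719729
CCTT	1.1731885974295437
CGAA	4.881712207337841
CGAC	6.697081966325641
CGAG	7.40757529460825
CGAT	6.755816716235131
CGCA	7.206781441811472
CGCC	1.8267273847013712
CGCG	7.27580555784516
CGCT	6.564540888881311
CGGA	2.6796134877949953
CGGC	7.430384159088135
CGGG	4.474623198155314
CGGT	6.631791535299271
CGTA	2.7278508697636425
CGTC	4.601072431541979
CGTG	3.107120940228924
CGTT	5.864502581069246
CTAA	3.9589559726882726
CTAC	1.0726297448854893
CTAG	1.3606378191616386
CTAT	6.065726656001061
CTCA	6.304552324814722
CTCC	6.247964904410765
CTCG	7.40757529460825
CTCT	1.6549285186920315
CTGA	4.7119641792960465
CTGC	4.191637918818742
CTGG	5.831009793560952
CTGT	1.8483247836120427
CTTA	5.181909395381808
CTTC	4.047295569675043
CTTG	3.77099291770719
CTTT	2.7526558935642242
GAAA	2.7268499550409615
GAAC	4.7396558506879956
GAAG	4.047295569675043
GAAT	4.966972351307049
GACA	6.232233946211636
GACC	2.537174493074417
GACG	4.601072431541979
GACT	3.1505364344920963
GAGA	2.206689964979887
GAGC	6.04844850837253
GAGG	1.1844816978555173
GAGT	2.1489499495364726
GATA	4.909699809039012
GATC	2.7639282301533967
GATG	6.551711631240323
GATT	4.356867926660925
GCAA	7.60492287366651
GCAC	5.852686725789681
GCAG	4.191637918818742
GCAT	2.469312011031434
GCCA	5.089007325004786
GCCC	6.381295785075054
GCCG	7.430384159088135
GCCT	1.2983933696523309
GCGA	6.920213890494779
GCGC	6.777645087568089
GCGG	6.41512509342283
GCGT	7.120166105451062
GCTA	1.4280873876996338
GCTC	6.04844850837253
GCTG	1.6437752253841609
GCTT	1.6608769472222775
GGAA	4.833669428480789
GGAC	4.850167589262128
GGAG	6.247964904410765
GGAT	4.917425858322531
GGCA	4.371452629799023
GGCC	4.6179166964720935
GGCG	1.8267273847013712
GGCT	6.442757433047518
GGGA	7.65464201127179
GGGC	6.381295785075054
GGGG	3.295001340797171
GGGT	2.638688056729734
GGTA	1.24531334429048
GGTC	2.537174493074417
GGTG	4.508875816594809
GGTT	7.5691419292707
GTAA	4.004082728177309
GTAC	3.8216706144157797
GTAG	1.0726297448854893
GTAT	7.679225921398029
GTCA	3.885323471389711
GTCC	4.850167589262128
GTCG	6.697081966325641
GTCT	7.99118856433779
GTGA	2.3558504614047706
GTGC	5.852686725789681
GTGG	6.185481884283945
GTGT	2.6797051534522325
GTTA	4.676788191078231
GTTC	4.7396558506879956
GTTG	5.332334670238197
GTTT	5.2635932308621705
TAAA	6.703639269107953
TAAC	4.676788191078231
TAAG	5.181909395381808
TAAT	3.88102945452556
TACA	1.2503323499113321
TACC	1.24531334429048
TACG	2.7278508697636425
TACT	7.332704310305417
TAGA	3.6621126462705433
TAGC	1.4280873876996338
TAGG	3.695137210888788
TAGT	4.235411217669025
TATA	5.252345346380025
TATC	4.909699809039012
TATG	4.424036076758057
TATT	1.265191508922726
TCAA	4.189253930468112
TCAC	2.3558504614047706
TCAG	4.7119641792960465
TCAT	6.677516915136948
TCCA	3.5172535839956254
TCCC	7.65464201127179
TCCG	2.6796134877949953
TCCT	3.6084637325257063
TCGA	2.9805568407755345
TCGC	6.920213890494779
TCGG	2.7161956147756428
TCGT	7.087569991359487
TCTA	3.6621126462705433
TCTC	2.206689964979887
TCTG	2.520211693365127
TCTT	7.528990632388741
TGAA	2.4191903369501233
TGAC	3.885323471389711
TGAG	6.304552324814722
TGAT	3.627398237818852
TGCA	4.159019893500954
TGCC	4.371452629799023
TGCG	7.206781441811472
TGCT	5.313126390334219
TGGA	3.5172535839956254
TGGC	5.089007325004786
TGGG	2.0062128943391144
TGGT	1.048961317865178
TGTA	1.2503323499113321
TGTC	6.232233946211636
TGTG	6.482738885330036
TGTT	5.812422264367342
TTAA	4.1512391834985465
TTAC	4.004082728177309
TTAG	3.9589559726882726
TTAT	2.92370141367428
TTCA	2.4191903369501233
TTCC	4.833669428480789
TTCG	4.881712207337841
TTCT	7.47424594219774
TTGA	4.189253930468112
TTGC	7.60492287366651
TTGG	3.1373709852341563
TTGT	7.642374865245074
TTTA	6.703639269107953
TTTC	2.7268499550409615
TTTG	5.252013512887061
TTTT	5.412020446034148
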