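1 1 0 0 0 0.5 -1
2 3 -2.05153872569981 3.37759206941826 -3.06317819748653 0.5 1
3 3 -1.17683943719039 2.91666942296244 -7.96444859083 0.5 2
4 3 -2.25370352705328 1.54033727263594 -12.649112244065 0.5 3
5 3 0.906137080047222 0.761982523002143 -11.9667645693325 0.5 3
6 3 -5.44907916521223 5.28744939321585 -6.19513668453812 0.5 2
7 3 -8.41961795442472 7.54315875845746 -9.52495267965636 0.5 6
8 3 -8.52665531225595 12.461550207069 -10.4182435406046 0.5 7
9 3 -9.89893771799592 11.5050037669587 -6.85748249880687 0.5 7
10 3 -4.5011650962091 5.23448938000042 -11.1041746916008 0.5 6
11 3 -5.79935544942687 9.99099996336372 -11.9350229792955 0.5 10
12 3 -6.70065672220858 8.18362039427759 -14.490155029374 0.5 10
13 3 2.734042396433 3.9197114555575 1.4699912515652 0.5 1
14 3 7.56674099231951 4.90954821929859 2.28561828793852 0.5 13
15 3 6.37871351858599 7.33963193501257 1.61322646213803 0.5 13
16 3 10.7569880258711 9.75110489857751 1.48868536509658 0.5 15
17 3 9.25808863225789 11.413582649373 1.2783764483573 0.5 15
18 3 12.9499875384912 13.29975732879 4.07341268155349 0.5 17
19 3 11.9885630296285 15.5838059188675 1.67048287252073 0.5 17
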