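"wavelength_nm","R","G","B"
400,2.23363143620316e-10,8.36483472297277e-05,0.135335283236613
410,1.94976778601724e-09,0.000335462627902512,0.249352208777296
420,1.52299797447126e-08,0.0012038599948282,0.411112290507187
430,1.0645371411076e-07,0.0038659201394728,0.606530659712633
440,6.65836146985732e-07,0.0111089965382423,0.800737402916808
450,3.72665317207867e-06,0.0285655007845504,0.945959468906765
460,1.86644691135205e-05,0.0657285286165304,1
470,8.36483472297277e-05,0.135335283236613,0.945959468906765
480,0.000335462627902512,0.249352208777296,0.800737402916808
490,0.0012038599948282,0.411112290507187,0.606530659712633
500,0.0038659201394728,0.606530659712633,0.411112290507187
510,0.0111089965382423,0.800737402916808,0.249352208777296
520,0.0285655007845504,0.945959468906765,0.135335283236613
530,0.0657285286165304,1,0.0657285286165304
540,0.135335283236613,0.945959468906765,0.0285655007845504
550,0.249352208777296,0.800737402916808,0.0111089965382423
560,0.411112290507187,0.606530659712633,0.0038659201394728
570,0.606530659712633,0.411112290507187,0.0012038599948282
580,0.800737402916808,0.249352208777296,0.000335462627902512
590,0.945959468906765,0.135335283236613,8.36483472297277e-05
600,1,0.0657285286165304,1.86644691135205e-05
610,0.945959468906765,0.0285655007845504,3.72665317207867e-06
620,0.800737402916808,0.0111089965382423,6.65836146985732e-07
630,0.606530659712633,0.0038659201394728,1.0645371411076e-07
640,0.411112290507187,0.0012038599948282,1.52299797447126e-08
650,0.249352208777296,0.000335462627902512,1.94976778601724e-09
660,0.135335283236613,8.36483472297277e-05,2.23363143620316e-10
670,0.0657285286165304,1.86644691135205e-05,2.28973484564555e-11
680,0.0285655007845504,3.72665317207867e-06,2.10040929273226e-12
690,0.0111089965382423,6.65836146985732e-07,1.72412093903551e-13
700,0.0038659201394728,1.0645371411076e-07,1.26641655490942e-14
710,0.0012038599948282,1.52299797447126e-08,8.32396967698111e-16
720,0.000335462627902512,1.94976778601724e-09,4.89586526458611e-17
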