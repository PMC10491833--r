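# S-cone fundamental, Smith-Pokorny-type: peak-normalized CIE 1931 z-bar (S prop. to Judd z-bar)
      380	0.0036183103
      385	0.0059183216
      390	0.011247616
      395	0.020313026
      400	0.038062381
      405	0.061819814
      410	0.11634691
      415	0.20829126
      420	0.36216762
      425	0.58288455
      430	0.7772916
      435	0.91044542
      440	0.98006283
      445	        1
      450	0.99411534
      455	0.97840233
      460	0.93638506
      465	0.85723101
      470	0.72233816
      475	0.58448334
      480	0.45604735
      485	0.34567486
      490	0.26095591
      495	0.19819365
      500	0.15258611
      505	0.1190957
      510	0.088746774
      515	0.062661281
      520	0.043896556
      525	0.03211601
      530	0.023650847
      535	0.016739594
      540	0.01138786
      545	0.0075171098
      550	0.0049085605
      555	0.0032256255
      560	0.0021878156
      565	0.0015426905
      570	0.0011780545
      575	0.001009761
      580	0.00092561427
      585	0.00078536968
      590	0.00061707618
      595	0.00056097835
      600	0.00044878268
      605	0.00033658701
      610	0.00019073264
      615	0.0001346348
      620	0.00010658589
      625	5.6097835e-05
      630	2.8048917e-05
      635	1.682935e-05
      640	1.1219567e-05
      645	5.6097835e-06
      650	        0
      655	        0
      660	        0
      665	        0
      670	        0
      675	        0
      680	        0
      685	        0
      690	        0
      695	        0
      700	        0
      705	        0
      710	        0
      715	        0
      720	        0
      725	        0
      730	        0
      735	        0
      740	        0
      745	        0
      750	        0
      755	        0
      760	        0
      765	        0
      770	        0
      775	        0
      780	        0
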