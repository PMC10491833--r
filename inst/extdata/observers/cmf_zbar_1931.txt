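# CIE 1931 2-deg colour-matching function z-bar, 5 nm
      380	  0.00645
      385	  0.01055
      390	  0.02005
      395	  0.03621
      400	  0.06785
      405	   0.1102
      410	   0.2074
      415	   0.3713
      420	   0.6456
      425	  1.03905
      430	   1.3856
      435	  1.62296
      440	  1.74706
      445	   1.7826
      450	  1.77211
      455	   1.7441
      460	   1.6692
      465	   1.5281
      470	  1.28764
      475	   1.0419
      480	  0.81295
      485	   0.6162
      490	  0.46518
      495	   0.3533
      500	    0.272
      505	   0.2123
      510	   0.1582
      515	   0.1117
      520	  0.07825
      525	  0.05725
      530	  0.04216
      535	  0.02984
      540	   0.0203
      545	   0.0134
      550	  0.00875
      555	  0.00575
      560	   0.0039
      565	  0.00275
      570	   0.0021
      575	   0.0018
      580	  0.00165
      585	   0.0014
      590	   0.0011
      595	    0.001
      600	   0.0008
      605	   0.0006
      610	  0.00034
      615	  0.00024
      620	  0.00019
      625	   0.0001
      630	    5e-05
      635	    3e-05
      640	    2e-05
      645	    1e-05
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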