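# CIE 1924 photopic luminous efficiency V(lambda), 5 nm, peak 1 at 555 nm
      380	  3.9e-05
      385	  6.4e-05
      390	  0.00012
      395	 0.000217
      400	 0.000396
      405	  0.00064
      410	  0.00121
      415	  0.00218
      420	    0.004
      425	   0.0073
      430	   0.0116
      435	  0.01684
      440	    0.023
      445	   0.0298
      450	    0.038
      455	    0.048
      460	     0.06
      465	   0.0739
      470	  0.09098
      475	   0.1126
      480	  0.13902
      485	   0.1693
      490	  0.20802
      495	   0.2586
      500	    0.323
      505	   0.4073
      510	    0.503
      515	   0.6082
      520	     0.71
      525	   0.7932
      530	    0.862
      535	  0.91485
      540	    0.954
      545	   0.9803
      550	  0.99495
      555	        1
      560	    0.995
      565	   0.9786
      570	    0.952
      575	   0.9154
      580	     0.87
      585	   0.8163
      590	    0.757
      595	   0.6949
      600	    0.631
      605	   0.5668
      610	    0.503
      615	   0.4412
      620	    0.381
      625	    0.321
      630	    0.265
      635	    0.217
      640	    0.175
      645	   0.1382
      650	    0.107
      655	   0.0816
      660	    0.061
      665	  0.04458
      670	    0.032
      675	   0.0232
      680	    0.017
      685	  0.01192
      690	  0.00821
      695	 0.005723
      700	 0.004102
      705	 0.002929
      710	 0.002091
      715	 0.001484
      720	 0.001047
      725	  0.00074
      730	  0.00052
      735	 0.000361
      740	 0.000249
      745	 0.000172
      750	  0.00012
      755	  8.5e-05
      760	    6e-05
      765	  4.2e-05
      770	    3e-05
      775	  2.1e-05
      780	  1.5e-05
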