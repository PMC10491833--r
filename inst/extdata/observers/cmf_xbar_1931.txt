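# CIE 1931 2-deg colour-matching function x-bar, 5 nm
      380	 0.001368
      385	 0.002236
      390	 0.004243
      395	  0.00765
      400	  0.01431
      405	  0.02319
      410	  0.04351
      415	  0.07763
      420	  0.13438
      425	  0.21477
      430	   0.2839
      435	   0.3285
      440	  0.34828
      445	  0.34806
      450	   0.3362
      455	   0.3187
      460	   0.2908
      465	   0.2511
      470	  0.19536
      475	   0.1421
      480	  0.09564
      485	  0.05795
      490	  0.03201
      495	   0.0147
      500	   0.0049
      505	   0.0024
      510	   0.0093
      515	   0.0291
      520	  0.06327
      525	   0.1096
      530	   0.1655
      535	  0.22575
      540	   0.2904
      545	   0.3597
      550	  0.43345
      555	  0.51205
      560	   0.5945
      565	   0.6784
      570	   0.7621
      575	   0.8425
      580	   0.9163
      585	   0.9786
      590	   1.0263
      595	   1.0567
      600	   1.0622
      605	   1.0456
      610	   1.0026
      615	   0.9384
      620	  0.85445
      625	   0.7514
      630	   0.6424
      635	   0.5419
      640	   0.4479
      645	   0.3608
      650	   0.2835
      655	   0.2187
      660	   0.1649
      665	   0.1212
      670	   0.0874
      675	   0.0636
      680	  0.04677
      685	   0.0329
      690	   0.0227
      695	  0.01584
      700	 0.011359
      705	 0.008111
      710	  0.00579
      715	 0.004109
      720	 0.002899
      725	 0.002049
      730	  0.00144
      735	    0.001
      740	  0.00069
      745	 0.000476
      750	 0.000332
      755	 0.000235
      760	 0.000166
      765	 0.000117
      770	  8.3e-05
      775	  5.9e-05
      780	  4.2e-05
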