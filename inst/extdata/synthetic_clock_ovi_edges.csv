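bodyId_pre,instance_pre,bodyId_post,instance_post,weight
5813056917,LNd4,423101189,oviIN,30
5813021192,LNd5,423101189,oviIN,25
423101189,oviIN,5813056917,LNd4,8
423101189,oviIN,5813021192,LNd5,5
296544364,LNd1,423102189,pC1b,6
296544365,LNd2,423102189,pC1b,12
5813069648,LNd3,423102189,pC1b,4
423102189,pC1b,296544365,LNd2,7
423101189,oviIN,480029788,LPN-1,60
423101189,oviIN,480029789,LPN-2,40
423101189,oviIN,480029790,LPN-3,20
423101189,oviIN,481121022,LPN-L,15
480029790,LPN-3,423101189,oviIN,16
540226544,LNd6,423101189,oviIN,2
5813064789,5th-sLNv,423102189,pC1b,1
1664980698,sLNv-1,423103189,oviDN-1,2
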