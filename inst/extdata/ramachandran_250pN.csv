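# Ramachandran density fixture, pulling force 250 pN, 10 deg bins
phi_mid_deg,psi_mid_deg,weight
-175.0,85.0,1.3109044097e-09
-175.0,95.0,1.0413803598e-07
-175.0,105.0,4.1309919704e-06
-175.0,115.0,8.1828752205e-05
-175.0,125.0,8.0940170785e-04
-175.0,135.0,3.9978722644e-03
-175.0,145.0,9.8605314177e-03
-175.0,155.0,1.2144463620e-02
-175.0,165.0,7.4690086963e-03
-175.0,175.0,2.2937928874e-03
-165.0,85.0,4.9045420883e-09
-165.0,95.0,3.8961603657e-07
-165.0,105.0,1.5455454902e-05
-165.0,115.0,3.0614937004e-04
-165.0,125.0,3.0282488281e-03
-165.0,135.0,1.4957408518e-02
-165.0,145.0,3.6891623060e-02
-165.0,155.0,4.5436595165e-02
-165.0,165.0,2.7944117998e-02
-165.0,175.0,8.5818643027e-03
-155.0,85.0,9.1628909295e-09
-155.0,95.0,7.2789858528e-07
-155.0,105.0,2.8874591141e-05
-155.0,115.0,5.7196232295e-04
-155.0,125.0,5.6575136312e-03
-155.0,135.0,2.7944117998e-02
-155.0,145.0,6.8922625644e-02
-155.0,155.0,8.4886735236e-02
-155.0,165.0,5.2206485483e-02
-155.0,175.0,1.6033033291e-02
-145.0,85.0,8.5481705399e-09
-145.0,95.0,6.7906529615e-07
-145.0,105.0,2.6937451427e-05
-145.0,115.0,5.3359049197e-04
-145.0,125.0,5.2779621326e-03
-145.0,135.0,2.6069401903e-02
-145.0,145.0,6.4298741806e-02
-145.0,155.0,7.9191850581e-02
-145.0,165.0,4.8704054717e-02
-145.0,175.0,1.4957408518e-02
-135.0,85.0,3.9821759830e-09
-135.0,95.0,3.1634342126e-07
-135.0,105.0,1.2548845600e-05
-135.0,115.0,2.4857380190e-04
-135.0,125.0,2.4587453090e-03
-135.0,135.0,1.2144463770e-02
-135.0,145.0,2.9953650038e-02
-135.0,155.0,3.6891623467e-02
-135.0,165.0,2.2688845213e-02
-135.0,175.0,6.9679275654e-03
-125.0,95.0,7.3588994296e-08
-125.0,105.0,2.9191628904e-06
-125.0,115.0,5.7824394079e-05
-125.0,125.0,5.7196728918e-04
-125.0,135.0,2.8251262465e-03
-125.0,145.0,6.9680272944e-03
-125.0,155.0,8.5819640520e-03
-125.0,165.0,5.2779988283e-03
-125.0,175.0,1.6209097599e-03
-115.0,95.0,8.5509172828e-09
-115.0,105.0,3.3950012301e-07
-115.0,115.0,6.7391701009e-06
-115.0,125.0,6.6886783654e-05
-115.0,135.0,3.3146858418e-04
-115.0,145.0,8.1838085833e-04
-115.0,155.0,1.0058574300e-03
-115.0,165.0,6.1639681342e-04
-115.0,175.0,1.8873303158e-04
-105.0,105.0,3.3168741068e-08
-105.0,115.0,1.1266695910e-06
-105.0,125.0,1.8657968199e-05
-105.0,135.0,1.2842375010e-04
-105.0,145.0,3.4429815270e-04
-105.0,155.0,3.5517277303e-04
-105.0,165.0,1.4495107555e-04
-105.0,175.0,2.5725686972e-05
-95.0,105.0,1.6502859435e-07
-95.0,115.0,8.9904357087e-06
-95.0,125.0,1.8046268528e-04
-95.0,135.0,1.3331754459e-03
-95.0,145.0,3.6238077366e-03
-95.0,155.0,3.6241227201e-03
-95.0,165.0,1.3336541601e-03
-95.0,175.0,1.8066740184e-04
-85.0,95.0,4.9664355129e-09
-85.0,105.0,7.3706179466e-07
-85.0,115.0,4.0241923774e-05
-85.0,125.0,8.0827898187e-04
-85.0,135.0,5.9724147854e-03
-85.0,145.0,1.6234704575e-02
-85.0,155.0,1.6234709131e-02
-85.0,165.0,5.9724217094e-03
-85.0,175.0,8.0828194284e-04
-75.0,95.0,8.1879268850e-09
-75.0,105.0,1.2151959324e-06
-75.0,115.0,6.6347447764e-05
-75.0,125.0,1.3326240998e-03
-75.0,135.0,9.8468342037e-03
-75.0,145.0,2.6766470469e-02
-75.0,155.0,2.6766470502e-02
-75.0,165.0,9.8468342537e-03
-75.0,175.0,1.3326241212e-03
-65.0,95.0,4.9662277907e-09
-65.0,105.0,7.3705355465e-07
-65.0,115.0,4.0241760552e-05
-65.0,125.0,8.0827736737e-04
-65.0,135.0,5.9724068109e-03
-65.0,145.0,1.6234684906e-02
-65.0,155.0,1.6234684906e-02
-65.0,165.0,5.9724068111e-03
-65.0,175.0,8.0827736745e-04
-55.0,105.0,1.6445887764e-07
-55.0,115.0,8.9791504756e-06
-55.0,125.0,1.8035105842e-04
-55.0,135.0,1.3326240881e-03
-55.0,145.0,3.6224478430e-03
-55.0,155.0,3.6224478430e-03
-55.0,165.0,1.3326240881e-03
-55.0,175.0,1.8035105842e-04
-45.0,105.0,1.3499606745e-08
-45.0,115.0,7.3705355443e-07
-45.0,125.0,1.4804116382e-05
-45.0,135.0,1.0938844644e-04
-45.0,145.0,2.9734862620e-04
-45.0,155.0,2.9734862620e-04
-45.0,165.0,1.0938844644e-04
-45.0,175.0,1.4804116382e-05
-35.0,115.0,2.2257088786e-08
-35.0,125.0,4.4704557861e-07
-35.0,135.0,3.3032448592e-06
-35.0,145.0,8.9791504756e-06
-35.0,155.0,8.9791504756e-06
-35.0,165.0,3.3032448592e-06
-35.0,175.0,4.4704557861e-07
-25.0,125.0,4.9662277853e-09
-25.0,135.0,3.6695735705e-08
-25.0,145.0,9.9749351550e-08
-25.0,155.0,9.9749351550e-08
-25.0,165.0,3.6695735705e-08
-25.0,175.0,4.9662277853e-09
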